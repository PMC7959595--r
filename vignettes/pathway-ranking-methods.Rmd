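---
title: "Methods: active-subnetwork pathway ranking for expression classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-subnetwork pathway ranking for expression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

High-dimensional two-class expression data (thousands of genes, tens of
samples) invite overfitting when features are selected one gene at a time,
and the resulting gene lists are hard to interpret biologically. `pathrank`
selects *groups* of genes instead: pathways whose members form active
subnetworks in a protein–protein interaction network (PIN). A pathway group
enters the model only if (a) its genes are enriched within
significance-driven connected modules of the PIN and (b) the group, used as
a feature set, separates the two classes well under cross-validation. The
final classifier is built on the union of the top-k groups, and everything
is evaluated on samples the selection never saw.

The assumptions this rests on:

* expression values are continuous, already normalized, and comparable
  across samples (the package performs no normalization);
* gene identifiers in the matrix, the gene-set collection (GMT) and the PIN
  agree after uppercasing — no alias resolution is attempted, deliberately:
  alias maps are dataset- and release-specific and belong upstream;
* class labels are binary, with at least two samples per class.

# Stage by stage

## Per-gene statistics

Each gene gets a two-sided pooled-variance (Student) t-test comparing the
classes, computed vectorized over genes. The pooled test, rather than
Welch's, treats the two classes as sharing a variance — the conventional
choice for small balanced microarray designs, and the one that keeps
p-values exactly symmetric under label swap. A gene with zero pooled
variance has no defined statistic; its p is `NaN` and it is excluded from
seeding and enrichment rather than imputed. Missing expression values are a
hard error at load time for the same reason: silent imputation changes the
test in ways the user cannot see.

The seed threshold (`p_threshold = 0.2`, inclusive boundary) is
deliberately lenient: it feeds the *search*, not the inference. Genes at
p ≈ 0.2 rarely survive to the final model, but they let modules form around
borderline signal.

## Active-subnetwork search

Significance is mapped to `z(p) = qnorm(1 - p)` (p clamped to
`[1e-15, 1 - 1e-15]` so the transform is finite), and a module of k genes
scores `sum(z)/sqrt(k)` — approximately standard normal under the null for
any k, which is what makes modules of different sizes comparable and gives
the score-quantile filter a meaningful scale.

The search is greedy: seeds are the significant genes on the PIN, visited
in ascending p order (ties broken lexicographically, for determinism). A
module repeatedly makes the single best *addition*, where an addition is an
eligible gene within `max_depth` hops together with the genes of a shortest
connecting path, evaluated jointly; growth stops when no addition strictly
increases the score, or at `max_size` (default 25) genes.

`max_depth = 2` is the package's deliberate default. Radius 1 (plain
neighbor additions) cannot cross a non-significant linker gene: in a chain
*sig–null–sig* it stalls on the first gene, because adding the null linker
alone always lowers the score. Absorbing significant genes that are only
*connected through* interaction partners is the defining ability of
active-module search, so the expansion must look (at least) one gene past
the frontier and pull the connector in when the joint addition pays. On
random graphs this lifted the greedy optimum from roughly 88% to well above
90% of the exhaustive connected-subgraph optimum (the regression guard in
the test suite).

Two further deterministic choices: a gene claimed by one module is not
reused by later modules (prevents near-duplicate modules and makes
module membership unambiguous), and score ties between candidate additions
break on the sorted gene-name signature.

Modules are filtered by the 0.80 empirical score quantile and a minimum
significant-gene content of `ceiling(0.02 × n_significant)`; both mirror
the defaults documented for the reference active-subnetwork tooling and are
exposed in `subnetwork_config()`.

Because a single greedy pass is deterministic, repeated iterations would be
identical; each of the `iterations = 10` rounds therefore shuffles the seed
visiting order with a seed derived from the master seed. That is what makes
"lowest/highest adjusted p over iterations" and the occurrence count
informative: a pathway that is enriched under every visiting order is a far
stronger finding than one that appears once.

## Enrichment

Each filtered module's genes (the query) are tested against every pathway
they overlap by at least one gene, with the hypergeometric upper tail
`P(X >= overlap)`. The background universe is the intersection of dataset
genes with the union of pathway annotations — the conservative
over-representation convention: genes that could never be drawn into a
pathway should not inflate the universe. The tests of one module are
BH-adjusted together (FDR control is the field standard where the
adjustment method is not otherwise pinned down); adjusted values strictly
above the threshold (default 0.2) are discarded, and per pathway the
minimum adjusted p across modules is kept, then aggregated over iterations
into lowest/highest adjusted p and an occurrence count.

A pathway's reported member genes are its significant input genes (the
intersection of the significant-gene list with the pathway set): these are
the genes that actually become classifier features downstream, so the
reported list and the used features cannot drift apart.

## Ranking and top-k evaluation

Each enriched pathway group is scored by Monte Carlo cross-validation on
the outer-training data only: `r_iterations = 10` stratified 80/20 splits,
classifier fitted on the train part, confusion metrics on the test part,
means reported. Accuracy is the default sort key (configurable); ties break
by enrichment p, then pathway ID. Stratified inner splits clamp the
per-class training count to `[1, n_c - 1]`, so an inner test split can
never lose a class and no re-draw logic is needed.

The classifier defaults are fixed for reproducibility: random forest with
100 trees, or a linear SVM with cost 1 whose features are standardized with
training-split statistics (zero-variance features pass through unscaled).
AUC uses the positive-class probability (RF) or the oriented decision value
(SVM), with the Mann–Whitney rank estimate — ties count 0.5 per pair.
Metrics with zero denominators are `NaN`, and means skip `NaN` rather than
counting it as 0, so a degenerate split cannot bias a group's score
downward.

The outer loop is 10-fold *Monte Carlo* cross-validation — 10 independent
stratified 90/10 splits, not a partition — matching the repeated-split
design the method is defined with. Under-sampling (majority capped at
twice the minority, `floor(2 × n_min)`, uniform without replacement) is
applied to the training partition only, after the split: rebalancing the
test partition would misstate the deployment distribution. The per-k gene
count is the size of the *union* of the top-k groups' genes, so shared
genes are counted once and the count is nondecreasing in k.

A fold whose enrichment is empty contributes no rows (logged); with no
signal anywhere, the pipeline's documented output is an empty list, and the
command-line wrapper exits with a status distinct from a crash.

# Randomness and determinism

Every stochastic step (splits, under-sampling, seed-order shuffles,
classifier fits) draws from a seed derived deterministically from the
master seed by a fixed integer mix kept below 2^31. Two runs with the same
inputs and master seed produce byte-identical output tables; the test suite
asserts this.

# The synthetic generator

`synthetic_spec()` emulates the structure the pipeline is designed for:
i.i.d. Gaussian noise per gene, disjoint pathway gene sets, and planted
pathways whose genes get a mean shift of `effect_size × noise_sd` in the
positive class and are mutually wired (clique by default, chain as the
harder variant) in the generated PIN, plus uniformly random background
edges avoiding planted pairs. The defaults — 1,000 genes, 30 + 30 samples,
20 pathways of 15 genes, 1 planted, effect 2.0, `noise_sd = 1`, 2,000 extra
edges — are the package's standard benchmark condition; 2,000 edges gives a
mean degree near 4, a sparse PIN-like regime where modules cannot form by
density alone. Effect 2.0 over 15 genes and 60 samples is a strong but
realistic microarray-scale signal: single-gene t-tests find it easily, so
what the benchmark probes is whether the *grouping* stages preserve it.

What the generator does **not** emulate: gene–gene correlation within and
across pathways, heavy-tailed and heteroscedastic noise, batch structure,
probe-level artifacts, overlapping pathway membership, and hub-dominated
PIN topology. Passing tests on this generator therefore demonstrate the
pipeline's correctness and calibration (planted signal is recovered;
label-permuted null data scores at chance with uniform p-values), not its
power on real data with correlated noise.

# Problem sizes in the shipped tests

The test suite runs the full pipeline at the benchmark condition
(1,000 genes) for the planted-recovery and null-calibration checks — 10 and
20 single-fold runs respectively — and uses a 200-gene, 8-pathway
miniature for the determinism, partition-hygiene and schema contracts;
exhaustive oracles (hypergeometric enumeration to background 30, connected
subgraph enumeration to 12 nodes) cover the combinatorial primitives. These
sizes were chosen so the whole suite exercises every stage end to end in a
few minutes on one core.

# Known limitations

* Exact-match gene identifiers: symbol drift between matrix, GMT and PIN
  silently shrinks the effective background and gene groups.
* Greedy module search has no optimality guarantee; the shipped guard is
  statistical (≥ 0.8 × exhaustive optimum on ≥ 90% of small random graphs).
* Pathway groups are ranked independently; complementary pathways that are
  individually weak are only captured indirectly through the top-k union.
* The occurrence count depends on the number of iterations and seed
  shuffling; it is a stability indicator, not a calibrated probability.
* With very small minority classes, the 90/10 outer split leaves one or two
  test samples per class, so per-fold metrics are coarse; only their
  averages over folds are meaningful.
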