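# Aggregate-z scoring and the greedy active-subnetwork search.

test_that("gene_z maps p to the upper-tail normal quantile", {
  expect_equal(gene_z(0.5), 0)
  # bisection on the normal CDF as an independent inverse
  target <- 0.025
  lo <- -10; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (1 - stats::pnorm(mid) > target) lo <- mid else hi <- mid
  }
  expect_equal(gene_z(0.025), (lo + hi) / 2, tolerance = 1e-6)
  expect_true(is.finite(gene_z(1)))   # clamped
  expect_true(is.finite(gene_z(0)))
  expect_lt(gene_z(1 - 1e-16), -7)
})

test_that("subnetwork score is sum(z)/sqrt(k), order-invariant", {
  st <- stats_table(c("A", "B"), c(0.5, 0.025))
  expect_equal(score_subnetwork("A", st), 0)
  st2 <- stats_table(c("A", "B"), c(0.025, 0.025))
  expect_equal(score_subnetwork(c("A", "B"), st2),
               2 * gene_z(0.025) / sqrt(2), tolerance = 1e-10)
  expect_equal(score_subnetwork(c("A", "B"), st2),
               score_subnetwork(c("B", "A"), st2))
  expect_error(score_subnetwork(character(0), st), "empty")
})

test_that("greedy search handles isolated seeds and empty seed sets", {
  g <- graph_from_edges("B", "C")
  g <- igraph::add_vertices(g, 1, name = "A")
  st <- stats_table(c("A", "B", "C"), c(0.01, 0.9, 0.95))
  subs <- greedy_subnetworks(g, st, subnetwork_config())
  expect_length(subs, 1)
  expect_equal(subs[[1]]$genes, "A")
  none <- stats_table(c("A", "B", "C"), c(0.9, 0.9, 0.95))
  expect_warning(out <- greedy_subnetworks(g, none, subnetwork_config()),
                 "no significant gene")
  expect_length(out, 0)
})

test_that("on a path graph the greedy result dominates subgraphs holding its seed", {
  g <- graph_from_edges("A", "B", "B", "C", "C", "D")
  st <- stats_table(c("A", "B", "C", "D"), c(0.01, 0.5, 0.01, 0.9))
  subs <- greedy_subnetworks(g, st, subnetwork_config())
  best <- subs[[1]]
  seed <- best$genes[1]
  for (members in connected_subsets(g)) {
    if (seed %in% members) {
      expect_gte(best$score + 1e-12, score_subnetwork(members, st))
    }
  }
})

test_that("returned subnetworks are connected, disjoint and locally maximal", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, 0.35)
    igraph::V(g)$name <- LETTERS[seq_len(n)]
    st <- stats_table(LETTERS[seq_len(n)], runif(n))
    subs <- suppressWarnings(greedy_subnetworks(g, st, subnetwork_config()))
    claimed <- unlist(lapply(subs, `[[`, "genes"))
    expect_equal(anyDuplicated(claimed), 0)
    for (sub in subs) {
      expect_true(igraph::is_connected(igraph::induced_subgraph(g, sub$genes)))
      # no eligible neighbor addition improves the score
      nb <- setdiff(unique(unlist(
        lapply(igraph::adjacent_vertices(g, sub$genes), names))),
        c(sub$genes, claimed))
      for (cand in nb) {
        expect_lte(score_subnetwork(c(sub$genes, cand), st),
                   sub$score + 1e-12)
      }
      expect_equal(sub$score, score_subnetwork(sub$genes, st),
                   tolerance = 1e-12)
      expect_lte(sub$n_significant, length(sub$genes))
    }
  }
})

test_that("filtering keeps high-score, significant-rich subnetworks in order", {
  mk <- function(score, nsig, gene) list(genes = gene, score = score,
                                         n_significant = nsig)
  subs <- list(mk(10, 3, "A"), mk(8, 3, "B"), mk(6, 3, "C"),
               mk(4, 3, "D"), mk(2, 3, "E"))
  cfg <- subnetwork_config(score_quantile = 0.80, min_sig_frac = 0.02)
  kept <- filter_subnetworks(subs, cfg, n_sig_total = 10)
  # empirical 0.8-quantile of (10,8,6,4,2) is 8.4: only the score-10 module
  expect_equal(stats::quantile(c(10, 8, 6, 4, 2), 0.8, names = FALSE), 8.4)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$score, 10)
  # singleton kept iff it meets min_sig_frac
  one <- list(mk(5, 1, "A"))
  expect_length(filter_subnetworks(one, subnetwork_config(min_sig_frac = 0.02),
                                   n_sig_total = 10), 1)
  expect_warning(
    none <- filter_subnetworks(one, subnetwork_config(min_sig_frac = 0.5),
                               n_sig_total = 10),
    "removed")
  expect_length(none, 0)
  # no-op configuration is the identity
  ident <- filter_subnetworks(subs, subnetwork_config(score_quantile = 0,
                                                      min_sig_frac = 0),
                              n_sig_total = 10)
  expect_identical(ident, subs)
})
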