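# Synthetic two-class expression data with planted differentially expressed
# pathways. Gene values are i.i.d. Gaussian noise; the genes of each planted
# pathway get a mean shift in the positive class and are mutually connected
# in the generated interaction network, so every downstream stage (t-test,
# subnetwork search, enrichment, ranking, top-k models) has an analytically
# predictable expected outcome.

#' Specification of a synthetic dataset
#'
#' Defaults describe the standard benchmark condition used throughout the
#' package's tests: 1,000 genes, 30 + 30 samples, 20 disjoint pathways of 15
#' genes, one planted pathway shifted by 2 noise standard deviations and
#' wired as a clique, with 2,000 random background interactions (mean degree
#' about 4, a sparse PIN-like graph).
#'
#' @param n_genes total number of genes.
#' @param n_pos,n_neg samples per class.
#' @param n_pathways number of disjoint pathway gene sets.
#' @param pathway_size genes per pathway.
#' @param n_planted pathways whose genes are differentially expressed.
#' @param effect_size mean shift of planted genes in the positive class, in
#'   units of `noise_sd`.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param pin_extra_edges random background edges added to the network.
#' @param planted_connectivity `"clique"` (default) or `"path"`: how each
#'   planted pathway's genes are wired.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes = 1000, n_pos = 30, n_neg = 30,
                           n_pathways = 20, pathway_size = 15, n_planted = 1,
                           effect_size = 2, noise_sd = 1,
                           pin_extra_edges = 2000,
                           planted_connectivity = c("clique", "path"),
                           seed = 1) {
  planted_connectivity <- match.arg(planted_connectivity)
  if (n_planted > n_pathways) stop("n_planted exceeds n_pathways")
  if (n_pathways * pathway_size > n_genes) {
    stop("pathway_size * n_pathways exceeds n_genes")
  }
  stopifnot(n_pos >= 2, n_neg >= 2, noise_sd > 0, effect_size >= 0,
            pin_extra_edges >= 0)
  structure(list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 n_planted = as.integer(n_planted),
                 effect_size = effect_size, noise_sd = noise_sd,
                 pin_extra_edges = as.integer(pin_extra_edges),
                 planted_connectivity = planted_connectivity,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic dataset, pathway collection and network
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (an `ExpressionDataset`), `sets` (a
#'   `GeneSetCollection`), `pin` (igraph), and `truth` (IDs of the planted
#'   pathways).
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- c(sprintf("POS%03d", seq_len(spec$n_pos)),
               sprintf("NEG%03d", seq_len(spec$n_neg)))
  labels <- stats::setNames(rep(c("pos", "neg"), c(spec$n_pos, spec$n_neg)),
                            samples)
  with_seed(spec$seed, {
    vals <- matrix(stats::rnorm(length(samples) * spec$n_genes,
                                sd = spec$noise_sd),
                   nrow = length(samples),
                   dimnames = list(samples, genes))
    member_pool <- sample(genes, spec$n_pathways * spec$pathway_size)
    sets_list <- split(member_pool,
                       rep(seq_len(spec$n_pathways), each = spec$pathway_size))
    ids <- sprintf("PWY%03d", seq_len(spec$n_pathways))
    names(sets_list) <- ids
    planted <- ids[seq_len(spec$n_planted)]
    for (id in planted) {
      g <- sets_list[[id]]
      vals[labels == "pos", g] <- vals[labels == "pos", g] +
        spec$effect_size * spec$noise_sd
    }
    # network: planted pathways wired per connectivity, plus random edges
    edges <- matrix(character(0), ncol = 2)
    for (id in planted) {
      g <- sets_list[[id]]
      e <- if (spec$planted_connectivity == "clique") {
        t(utils::combn(g, 2))
      } else {
        cbind(g[-length(g)], g[-1])
      }
      edges <- rbind(edges, e)
    }
    planted_genes <- unlist(sets_list[planted], use.names = FALSE)
    if (spec$pin_extra_edges > 0) {
      got <- matrix(character(0), ncol = 2)
      while (nrow(got) < spec$pin_extra_edges) {
        a <- sample(genes, 2 * spec$pin_extra_edges, replace = TRUE)
        b <- sample(genes, 2 * spec$pin_extra_edges, replace = TRUE)
        ok <- a != b & !(a %in% planted_genes & b %in% planted_genes)
        got <- rbind(got, cbind(a[ok], b[ok]))
      }
      edges <- rbind(edges, got[seq_len(spec$pin_extra_edges), , drop = FALSE])
    }
    pin <- igraph::simplify(
      igraph::graph_from_edgelist(edges, directed = FALSE))
    list(
      data = expression_dataset(vals, labels),
      sets = structure(list(sets = sets_list,
                            descriptions = stats::setNames(
                              paste("synthetic pathway", ids), ids)),
                       class = "GeneSetCollection"),
      pin = pin,
      truth = planted
    )
  })
}

#' Write a synthetic dataset as pipeline-ready files
#'
#' Writes `expression.tsv`, `labels.tsv`, `pathways.gmt`, `pin.tsv` and
#' `truth.json` into `outdir`; the files round-trip through the package's
#' readers and are byte-identical for identical specs.
#'
#' @param outdir output directory (created if absent).
#' @param spec a [synthetic_spec()].
#' @return invisibly, the generated object list (as [simulate_dataset()]).
#' @export
write_synthetic_fixture <- function(outdir, spec = synthetic_spec()) {
  gen <- simulate_dataset(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression(gen$data, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "labels.tsv"))
  write_gmt(gen$sets, file.path(outdir, "pathways.gmt"))
  el <- igraph::as_edgelist(gen$pin)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  utils::write.table(el, file.path(outdir, "pin.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(planted = gen$truth, spec = unclass(spec)),
                       file.path(outdir, "truth.json"), auto_unbox = TRUE)
  invisible(gen)
}
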