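# Per-gene differential expression: pooled-variance (Student) two-sided
# t-tests seed the active-subnetwork search. Computed vectorized over the
# gene columns; a gene whose pooled variance is zero has no defined test and
# gets p = NaN, which downstream steps exclude.

#' Per-gene two-sided Student t-test
#'
#' Pooled-variance (equal-variance) t-test of positive vs negative samples
#' for every gene, on exactly the samples present in `data` — callers pass
#' the training partition so the held-out samples never touch the statistics.
#'
#' @param data an `ExpressionDataset` with at least 2 samples per class.
#' @return a data frame (one row per gene, input order) with columns `gene`,
#'   `t_statistic` and `p_value`. Genes with zero pooled variance have
#'   `NaN` in both columns.
#' @export
t_test_genes <- function(data) {
  pos <- data$values[data$labels == data$positive, , drop = FALSE]
  neg <- data$values[data$labels == data$negative, , drop = FALSE]
  n1 <- nrow(pos); n2 <- nrow(neg)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per class for the t-test")
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  v1 <- apply(pos, 2, stats::var); v2 <- apply(neg, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df = df)
  zero <- sp2 == 0
  if (any(zero)) {
    tt[zero] <- NaN
    p[zero] <- NaN
    message(sum(zero), " gene(s) with zero pooled variance; p set to NaN")
  }
  data.frame(gene = dataset_genes(data), t_statistic = unname(tt),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Genes passing a significance threshold
#'
#' The boundary is inclusive: a gene with p exactly equal to the threshold is
#' significant. NaN p-values are excluded.
#'
#' @param stats data frame from [t_test_genes()].
#' @param threshold p-value cut-off in (0, 1]; default 0.2, the lenient seed
#'   threshold used before subnetwork search.
#' @return character vector of significant gene symbols.
#' @export
significant_genes <- function(stats, threshold = 0.2) {
  stopifnot(threshold > 0, threshold <= 1)
  ok <- !is.na(stats$p_value)
  if (!any(ok)) {
    warning("all p-values are NaN; no significant genes")
    return(character(0))
  }
  stats$gene[ok & stats$p_value <= threshold]
}

#' Write a per-gene statistics table
#'
#' Two-column TSV, `Gene<TAB>p-value`.
#' @param stats data frame from [t_test_genes()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_stats <- function(stats, path) {
  out <- data.frame(Gene = stats$gene, `p-value` = stats$p_value,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
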