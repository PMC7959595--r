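# Shared fixtures and independent oracles. Every oracle here recomputes the
# quantity by a different route than the package (enumeration, closed-form
# sums, direct step-up), so agreement is a real cross-check.

# --- tiny datasets -----------------------------------------------------------

# 4 pos + 4 neg samples; gene SEP separates the classes perfectly, the rest
# are fixed arbitrary values.
tiny_dataset <- function() {
  vals <- rbind(
    POS1 = c(SEP = 1, NOISE1 = 0.3, NOISE2 = -1.2),
    POS2 = c(1, -0.4, 0.8),
    POS3 = c(1, 1.1, 0.1),
    POS4 = c(1, 0.0, -0.5),
    NEG1 = c(0, 0.2, -0.9),
    NEG2 = c(0, -1.0, 1.4),
    NEG3 = c(0, 0.7, 0.6),
    NEG4 = c(0, -0.1, -0.2))
  colnames(vals) <- c("SEP", "NOISE1", "NOISE2")
  expression_dataset(vals, rep(c("pos", "neg"), each = 4))
}

# random two-class Gaussian dataset with named genes
random_dataset <- function(n_pos, n_neg, n_genes, seed) {
  set.seed(seed)
  vals <- matrix(rnorm((n_pos + n_neg) * n_genes), nrow = n_pos + n_neg,
                 dimnames = list(sprintf("S%03d", seq_len(n_pos + n_neg)),
                                 sprintf("G%03d", seq_len(n_genes))))
  expression_dataset(vals, rep(c("pos", "neg"), c(n_pos, n_neg)))
}

graph_from_edges <- function(...) {
  igraph::graph_from_edgelist(matrix(c(...), ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

stats_table <- function(genes, p) {
  data.frame(gene = genes, t_statistic = NA_real_, p_value = p,
             stringsAsFactors = FALSE)
}

gene_sets <- function(sets) {
  structure(list(sets = sets,
                 descriptions = stats::setNames(names(sets), names(sets))),
            class = "GeneSetCollection")
}

# --- oracles -----------------------------------------------------------------

# exact hypergeometric upper tail as a sum of counts of favorable draws
hyper_oracle_sum <- function(overlap, set_size, query_size, background) {
  i <- overlap:min(set_size, query_size)
  sum(choose(set_size, i) * choose(background - set_size, query_size - i)) /
    choose(background, query_size)
}

# literal enumeration of every possible draw (small backgrounds only)
hyper_oracle_enum <- function(overlap, set_size, query_size, background) {
  draws <- utils::combn(background, query_size)
  in_set <- colSums(draws <= set_size)  # set = elements 1..set_size
  mean(in_set >= overlap)
}

# Benjamini-Hochberg step-up written out directly
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# AUC by explicit enumeration of positive-negative pairs
auc_pairs_oracle <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# AUC by trapezoidal integration of the ROC curve
auc_trapezoid_oracle <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(pos >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(neg >= t), numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# all connected vertex subsets of a small graph (n <= 12), as a list of
# character vectors
connected_subsets <- function(g) {
  vs <- igraph::V(g)$name
  n <- length(vs)
  stopifnot(n <= 12)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- vs[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::is_connected(sub)) out[[length(out) + 1L]] <- members
  }
  out
}

# best aggregate-z score over all connected subgraphs (exhaustive optimum)
best_connected_score <- function(g, stats) {
  best <- -Inf
  for (members in connected_subsets(g)) {
    best <- max(best, score_subnetwork(members, stats))
  }
  best
}
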