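# Ranking pathway gene groups by Monte Carlo cross-validated classification
# performance. Each enriched pathway defines a gene group; the group's score
# is the mean of a classification metric over repeated stratified
# train/test splits of the (outer-training) data restricted to that group.

#' Configuration for the group-ranking step
#'
#' @param r_iterations number of inner Monte Carlo splits, default 10.
#' @param inner_train_frac training fraction of each inner split, default
#'   0.8.
#' @param classifier `"random_forest"` (default; 100 trees) or `"svm"`
#'   (linear kernel, cost 1, features standardized on the training split).
#' @param sort_metric metric used to sort groups, default `"acc"`; one of
#'   `acc`, `sen`, `spe`, `rec`, `prec`, `fm`.
#' @param seed master seed for the inner splits and classifier fits.
#' @return a `RankConfig` list.
#' @export
rank_config <- function(r_iterations = 10, inner_train_frac = 0.8,
                        classifier = c("random_forest", "svm"),
                        sort_metric = "acc", seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(r_iterations >= 1, inner_train_frac > 0, inner_train_frac < 1,
            sort_metric %in% c("acc", "sen", "spe", "rec", "prec", "fm"))
  structure(list(r_iterations = as.integer(r_iterations),
                 inner_train_frac = inner_train_frac,
                 classifier = classifier, sort_metric = sort_metric,
                 seed = as.integer(seed)),
            class = "RankConfig")
}

#' Restrict a dataset to a gene group
#'
#' Keeps the genes of `genes` present in the dataset; sample order is
#' untouched.
#'
#' @param data an `ExpressionDataset`.
#' @param genes character vector of gene symbols.
#' @param label used in the error message when nothing intersects.
#' @return the restricted `ExpressionDataset`.
#' @export
slice_genes <- function(data, genes, label = "gene group") {
  keep <- intersect(dataset_genes(data), toupper(genes))
  if (length(keep) == 0) {
    stop("no gene of ", label, " is present in the dataset")
  }
  expression_dataset(data$values[, keep, drop = FALSE], data$labels,
                     positive = data$positive)
}

# Fit the configured classifier on `train` and score `test`.
# Returns list(class = predicted labels, score = positive-class score used
# for AUC: RF class probability, SVM decision value oriented so larger
# means more positive).
fit_predict <- function(train, test, classifier, seed) {
  x_tr <- train$values
  y_tr <- factor(train$labels, levels = c(train$negative, train$positive))
  x_te <- test$values[, colnames(x_tr), drop = FALSE]
  if (classifier == "random_forest") {
    fit <- with_seed(seed, randomForest::randomForest(x_tr, y_tr, ntree = 100))
    prob <- stats::predict(fit, x_te, type = "prob")[, train$positive]
    cls <- as.character(stats::predict(fit, x_te, type = "response"))
  } else {
    ctr <- colMeans(x_tr)
    scl <- apply(x_tr, 2, stats::sd)
    scl[scl == 0] <- 1
    x_tr_s <- scale(x_tr, center = ctr, scale = scl)
    x_te_s <- scale(x_te, center = ctr, scale = scl)
    fit <- with_seed(seed, e1071::svm(x_tr_s, y_tr, kernel = "linear",
                                      cost = 1, scale = FALSE))
    pr <- stats::predict(fit, x_te_s, decision.values = TRUE)
    dvm <- attr(pr, "decision.values")
    dv <- dvm[, 1]
    # decision value favors the class named first in the column label;
    # orient it toward the positive class
    if (!startsWith(colnames(dvm)[1], paste0(train$positive, "/"))) dv <- -dv
    prob <- dv
    cls <- as.character(pr)
  }
  list(class = cls, score = unname(prob))
}

#' Score one gene group by Monte Carlo cross-validation
#'
#' Runs `r_iterations` stratified random splits of `data` restricted to
#' `genes`, fits the configured classifier on each training part and
#' averages the confusion metrics over the test parts.
#'
#' @param data an `ExpressionDataset` (pass the outer-training partition
#'   only, so held-out samples never leak into the ranking).
#' @param genes the group's gene symbols.
#' @param cfg a [rank_config()].
#' @return named numeric vector with mean `acc`, `sen`, `spe`, `rec`,
#'   `prec`, `fm` and the number of genes used (`n_genes`). NaN metrics are
#'   skipped in the averaging.
#' @export
score_gene_group <- function(data, genes, cfg = rank_config()) {
  sliced <- slice_genes(data, genes)
  mets <- matrix(NA_real_, nrow = cfg$r_iterations, ncol = 6,
                 dimnames = list(NULL, c("acc", "sen", "spe", "rec", "prec", "fm")))
  for (it in seq_len(cfg$r_iterations)) {
    it_seed <- derive_seed(cfg$seed, it)
    sp <- stratified_split(sliced$labels, cfg$inner_train_frac, it_seed)
    pred <- fit_predict(subset_samples(sliced, sp$train),
                        subset_samples(sliced, sp$test),
                        cfg$classifier, derive_seed(it_seed, 7))
    cc <- confusion_counts(sliced$labels[sp$test], pred$class, sliced$positive)
    m <- confusion_metrics(cc[["tp"]], cc[["fp"]], cc[["tn"]], cc[["fn"]])
    mets[it, ] <- m[c("acc", "sensitivity", "specificity", "recall",
                      "precision", "f_measure")]
  }
  means <- colMeans(mets, na.rm = TRUE)
  c(means, n_genes = ncol(sliced$values))
}

#' Rank enriched pathway groups by cross-validated performance
#'
#' One score per pathway, computed by [score_gene_group()] on the pathway's
#' member genes, sorted by the configured metric descending; ties are broken
#' by `lowest_adj_p` ascending, then pathway ID. Pathways whose member genes
#' are all absent from the dataset are skipped with a warning.
#'
#' @param data an `ExpressionDataset` (outer-training partition).
#' @param enriched data frame from [run_enrichment()].
#' @param cfg a [rank_config()].
#' @return data frame with columns `pathway_id`, `acc`, `sen`, `spe`, `rec`,
#'   `prec`, `fm`, `n_genes`, `lowest_adj_p`, sorted as described.
#' @export
rank_groups <- function(data, enriched, cfg = rank_config()) {
  if (nrow(enriched) == 0) stop("no enriched pathways to rank")
  rows <- list()
  for (i in seq_len(nrow(enriched))) {
    genes <- enriched$member_genes[[i]]
    sc <- tryCatch(score_gene_group(data, genes, cfg), error = function(e) NULL)
    if (is.null(sc)) {
      warning("pathway ", enriched$pathway_id[i],
              " skipped: no member gene present in the dataset")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = enriched$pathway_id[i], t(sc),
      lowest_adj_p = enriched$lowest_adj_p[i], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("every pathway group failed slicing")
  out <- do.call(rbind, rows)
  ord <- order(-out[[cfg$sort_metric]], out$lowest_adj_p, out$pathway_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a rank table
#'
#' TSV with columns `ID Acc Sen Spe Rec Prec Fm`.
#' @param ranked data frame from [rank_groups()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rank_table <- function(ranked, path) {
  out <- data.frame(ID = ranked$pathway_id, Acc = ranked$acc, Sen = ranked$sen,
                    Spe = ranked$spe, Rec = ranked$rec, Prec = ranked$prec,
                    Fm = ranked$fm, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
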