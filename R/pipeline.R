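# The outer evaluation loop: repeated stratified 90/10 Monte Carlo splits.
# Within each split the training partition alone drives every statistic —
# under-sampling, per-gene t-tests, subnetwork enrichment and group ranking —
# and classifiers built on the accumulated top-k groups are scored on the
# untouched test partition. Pathway and gene appearance frequencies are
# tallied across the splits.

#' Configuration for the full pipeline
#'
#' @param outer_folds number of independent Monte Carlo splits, default 10.
#' @param outer_train_frac training fraction of each split, default 0.9.
#' @param top_k_max evaluate models on the top 1..k groups, default 10.
#' @param undersample_ratio majority:minority cap applied to the training
#'   partition, default 2 (a 1:2 under-sampling).
#' @param master_seed seed from which every fold's randomness derives.
#' @param subnet a [subnetwork_config()] for the enrichment stage.
#' @param rank a [rank_config()] for the ranking stage; its `classifier` is
#'   also used for the top-k models.
#' @param p_threshold seed significance threshold forwarded to `subnet`.
#' @param enrich_threshold adjusted-p cut-off for enrichment, default 0.2.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(outer_folds = 10, outer_train_frac = 0.9,
                            top_k_max = 10, undersample_ratio = 2,
                            master_seed = 1,
                            subnet = subnetwork_config(p_threshold = p_threshold),
                            rank = rank_config(),
                            p_threshold = 0.2, enrich_threshold = 0.2) {
  stopifnot(outer_folds >= 1, outer_train_frac > 0, outer_train_frac < 1,
            top_k_max >= 1, undersample_ratio >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 outer_train_frac = outer_train_frac,
                 top_k_max = as.integer(top_k_max),
                 undersample_ratio = undersample_ratio,
                 master_seed = as.integer(master_seed),
                 subnet = subnet, rank = rank,
                 enrich_threshold = enrich_threshold),
            class = "PipelineConfig")
}

#' Cap the majority class by random under-sampling
#'
#' When the majority class exceeds `ratio` times the minority class, it is
#' subsampled uniformly without replacement to exactly
#' `floor(ratio * n_minority)`; otherwise the dataset is returned unchanged.
#' Sample order is preserved.
#'
#' @param data an `ExpressionDataset`.
#' @param ratio majority:minority cap, default 2.
#' @param seed integer seed.
#' @return an `ExpressionDataset`.
#' @export
undersample <- function(data, ratio = 2, seed = 1) {
  counts <- table(data$labels)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  cap <- floor(ratio * min(counts))
  if (max(counts) <= cap) return(data)
  maj_idx <- which(data$labels == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, cap)))
  keep <- sort(c(which(data$labels == minority), keep_maj))
  subset_samples(data, keep)
}

#' Evaluate classifiers on the accumulated top-k groups
#'
#' For i = 1..min(`top_k_max`, number of ranked groups): the gene list is the
#' union of the member genes of the i best-ranked pathways; the configured
#' classifier is fitted on the training partition restricted to that list
#' and scored on the test partition (confusion metrics plus AUC from the
#' positive-class scores).
#'
#' @param train,test disjoint `ExpressionDataset` partitions.
#' @param ranked data frame from [rank_groups()].
#' @param enriched data frame from [run_enrichment()] (provides member
#'   genes).
#' @param cfg a [pipeline_config()].
#' @param seed integer seed for the classifier fits.
#' @return data frame with one row per k: `k`, `acc`, `sen`, `spe`, `rec`,
#'   `prec`, `fm`, `auc`, `n_genes`.
#' @export
evaluate_topk <- function(train, test, ranked, enriched, cfg, seed = 1) {
  stopifnot(nrow(ranked) >= 1)
  if (length(intersect(dataset_samples(train), dataset_samples(test))) > 0) {
    stop("train and test partitions overlap")
  }
  k_max <- min(cfg$top_k_max, nrow(ranked))
  if (nrow(ranked) < cfg$top_k_max) {
    warning("only ", nrow(ranked), " ranked group(s) available; evaluating k <= ",
            nrow(ranked))
  }
  members <- stats::setNames(enriched$member_genes, enriched$pathway_id)
  gene_list <- character(0)
  out <- vector("list", k_max)
  for (i in seq_len(k_max)) {
    gene_list <- union(gene_list, members[[ranked$pathway_id[i]]])
    tr <- slice_genes(train, gene_list, label = paste0("top-", i, " union"))
    te <- slice_genes(test, gene_list, label = paste0("top-", i, " union"))
    pred <- fit_predict(tr, te, cfg$rank$classifier, derive_seed(seed, i))
    cc <- confusion_counts(te$labels, pred$class, te$positive)
    m <- confusion_metrics(cc[["tp"]], cc[["fp"]], cc[["tn"]], cc[["fn"]])
    a <- rank_auc(pred$score[te$labels == te$positive],
                  pred$score[te$labels != te$positive])
    out[[i]] <- data.frame(k = i, acc = m[["acc"]], sen = m[["sensitivity"]],
                           spe = m[["specificity"]], rec = m[["recall"]],
                           prec = m[["precision"]], fm = m[["f_measure"]],
                           auc = a, n_genes = length(gene_list))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pathway-ranking classification pipeline
#'
#' For each outer fold: stratified split, under-sampling of the training
#' partition, per-gene t-tests, repeated active-subnetwork enrichment, group
#' ranking, and top-k evaluation on the held-out partition. Per-k metrics
#' are averaged over the folds; the frequency with which each pathway (and
#' each of its member genes) enters a fold's evaluated top list is tallied.
#'
#' @param data an `ExpressionDataset`.
#' @param sets a `GeneSetCollection`.
#' @param pin an igraph PIN.
#' @param cfg a [pipeline_config()].
#' @return list with elements
#'   \describe{
#'     \item{topk}{data frame of per-k metric means over folds (`k`, `acc`,
#'       `sen`, `spe`, `rec`, `prec`, `fm`, `auc`, `n_genes`, `n_folds`).}
#'     \item{frequency}{data frame `pathway_id`, `count`, plus a list-column
#'       `gene_counts` of per-gene appearance counts.}
#'     \item{folds}{per-fold artifacts: sample IDs of the partitions, the
#'       gene-stat table, enrichment and rank tables and the per-k table.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
run_pipeline <- function(data, sets, pin, cfg = pipeline_config()) {
  folds <- vector("list", cfg$outer_folds)
  path_count <- new.env(parent = emptyenv())
  gene_count <- new.env(parent = emptyenv())
  for (f in seq_len(cfg$outer_folds)) {
    fold_seed <- derive_seed(cfg$master_seed, f)
    sp <- stratified_split(data$labels, cfg$outer_train_frac, fold_seed)
    train <- subset_samples(data, sp$train)
    test <- subset_samples(data, sp$test)
    train <- undersample(train, cfg$undersample_ratio, derive_seed(fold_seed, 11))
    stats_tab <- t_test_genes(train)
    sub_cfg <- cfg$subnet
    sub_cfg$seed <- derive_seed(fold_seed, 23)
    enriched <- suppressWarnings(
      run_enrichment(pin, stats_tab, sets, sub_cfg, cfg$enrich_threshold))
    fold <- list(train_samples = dataset_samples(train),
                 test_samples = dataset_samples(test),
                 gene_stats = stats_tab, enrichment = enriched,
                 rank_table = NULL, topk = NULL)
    if (nrow(enriched) == 0) {
      message("fold ", f, ": no enriched pathway; fold contributes no rows")
      folds[[f]] <- fold
      next
    }
    rk_cfg <- cfg$rank
    rk_cfg$seed <- derive_seed(fold_seed, 37)
    ranked <- suppressWarnings(rank_groups(train, enriched, rk_cfg))
    topk <- suppressWarnings(
      evaluate_topk(train, test, ranked, enriched, cfg,
                    seed = derive_seed(fold_seed, 53)))
    # frequency: one count per fold for every pathway in the evaluated top list
    top_ids <- ranked$pathway_id[seq_len(min(cfg$top_k_max, nrow(ranked)))]
    members <- stats::setNames(enriched$member_genes, enriched$pathway_id)
    for (id in top_ids) {
      assign(id, (if (exists(id, envir = path_count))
        get(id, envir = path_count) else 0L) + 1L, envir = path_count)
      for (g in members[[id]]) {
        key <- paste(id, g, sep = "\r")
        assign(key, (if (exists(key, envir = gene_count))
          get(key, envir = gene_count) else 0L) + 1L, envir = gene_count)
      }
    }
    fold$rank_table <- ranked
    fold$topk <- topk
    folds[[f]] <- fold
  }

  all_topk <- do.call(rbind, lapply(folds, `[[`, "topk"))
  if (is.null(all_topk) || nrow(all_topk) == 0) {
    warning("no fold produced an enriched pathway; empty result")
    topk_mean <- data.frame(k = integer(0), acc = numeric(0), sen = numeric(0),
                            spe = numeric(0), rec = numeric(0),
                            prec = numeric(0), fm = numeric(0),
                            auc = numeric(0), n_genes = numeric(0),
                            n_folds = integer(0))
  } else {
    ks <- sort(unique(all_topk$k))
    topk_mean <- do.call(rbind, lapply(ks, function(k) {
      rows <- all_topk[all_topk$k == k, , drop = FALSE]
      data.frame(k = k,
                 acc = mean(rows$acc, na.rm = TRUE),
                 sen = mean(rows$sen, na.rm = TRUE),
                 spe = mean(rows$spe, na.rm = TRUE),
                 rec = mean(rows$rec, na.rm = TRUE),
                 prec = mean(rows$prec, na.rm = TRUE),
                 fm = mean(rows$fm, na.rm = TRUE),
                 auc = mean(rows$auc, na.rm = TRUE),
                 n_genes = mean(rows$n_genes),
                 n_folds = nrow(rows))
    }))
  }

  ids <- ls(path_count)
  if (length(ids) == 0) {
    freq <- data.frame(pathway_id = character(0), count = integer(0),
                       gene_counts = I(list()))
  } else {
    counts <- vapply(ids, function(id) get(id, envir = path_count), integer(1))
    gkeys <- ls(gene_count)
    freq <- data.frame(pathway_id = ids, count = unname(counts),
                       stringsAsFactors = FALSE)
    freq$gene_counts <- I(lapply(ids, function(id) {
      mine <- gkeys[startsWith(gkeys, paste0(id, "\r"))]
      v <- vapply(mine, function(k) get(k, envir = gene_count), integer(1))
      names(v) <- sub("^.*\r", "", mine)
      sort(v, decreasing = TRUE)
    }))
    freq <- freq[order(-freq$count, freq$pathway_id), , drop = FALSE]
    rownames(freq) <- NULL
  }

  list(topk = topk_mean, frequency = freq, folds = folds, config = cfg)
}

#' Write the pipeline's output tables
#'
#' Writes into `outdir`: `gene_stats.tsv` and `enriched_pathways.tsv` (the
#' fold-1 training-partition artifacts), `rank_table_fold<f>.tsv` per fold,
#' `topk_performance.tsv` (per-k means with `#G`, the mean gene count),
#' `pathway_frequency.tsv` (`KEGG Pathway<TAB>count<TAB>Genes`), and
#' `run_log.txt` echoing the configuration.
#'
#' @param result list from [run_pipeline()].
#' @param outdir output directory (created if absent).
#' @return invisibly, `outdir`.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f1 <- result$folds[[1]]
  write_gene_stats(f1$gene_stats, file.path(outdir, "gene_stats.tsv"))
  write_enrichment(f1$enrichment, file.path(outdir, "enriched_pathways.tsv"))
  for (f in seq_along(result$folds)) {
    rk <- result$folds[[f]]$rank_table
    if (!is.null(rk)) {
      write_rank_table(rk, file.path(outdir, sprintf("rank_table_fold%d.tsv", f)))
    }
  }
  tk <- result$topk
  topk_out <- data.frame(k = tk$k, AUC = tk$auc, Acc = tk$acc, Sen = tk$sen,
                         Spe = tk$spe, Rec = tk$rec, Prec = tk$prec,
                         Fm = tk$fm, `#G` = tk$n_genes, check.names = FALSE)
  utils::write.table(topk_out, file.path(outdir, "topk_performance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  freq_out <- data.frame(
    `KEGG Pathway` = result$frequency$pathway_id,
    count = result$frequency$count,
    Genes = vapply(result$frequency$gene_counts,
                   function(v) paste(names(v), collapse = ","), character(1)),
    check.names = FALSE)
  utils::write.table(freq_out, file.path(outdir, "pathway_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result$config
  log_lines <- c(
    sprintf("outer_folds=%d outer_train_frac=%g top_k_max=%d undersample_ratio=%g",
            cfg$outer_folds, cfg$outer_train_frac, cfg$top_k_max,
            cfg$undersample_ratio),
    sprintf("master_seed=%d classifier=%s", cfg$master_seed, cfg$rank$classifier),
    sprintf("p_threshold=%g enrich_threshold=%g iterations=%d",
            cfg$subnet$p_threshold, cfg$enrich_threshold, cfg$subnet$iterations),
    sprintf("fold_seeds=%s",
            paste(vapply(seq_len(cfg$outer_folds),
                         function(f) derive_seed(cfg$master_seed, f),
                         integer(1)), collapse = ",")))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
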