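# Hypergeometric over-representation of pathway gene sets within each active
# subnetwork, with FDR adjustment inside each subnetwork's batch of tests and
# aggregation of the best adjusted p per pathway over repeated search
# iterations.

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= overlap)` when `query_size` genes are drawn without replacement
#' from a universe of `background` genes of which `set_size` belong to the
#' pathway.
#'
#' @param overlap observed overlap between the query and the pathway set.
#' @param set_size pathway size within the background.
#' @param query_size query size within the background.
#' @param background size of the background universe.
#' @return the p-value.
#' @export
hypergeom_test <- function(overlap, set_size, query_size, background) {
  if (set_size > background || query_size > background) {
    stop("set_size and query_size must not exceed the background")
  }
  if (overlap < 0 || overlap > min(set_size, query_size)) {
    stop("overlap must lie in [0, min(set_size, query_size)]")
  }
  if (overlap < max(0, set_size + query_size - background)) {
    stop("overlap below the minimum forced by the counts")
  }
  stats::phyper(overlap - 1, set_size, background - set_size, query_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped at 1, original order preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pathway enrichment of one batch of subnetworks
#'
#' Each subnetwork's gene list (intersected with the background) is the query
#' of a hypergeometric test against every pathway it overlaps by at least one
#' gene; the tests of one subnetwork are BH-adjusted together; adjusted
#' values above `threshold` are discarded; per pathway the minimum adjusted
#' p across subnetworks is kept.
#'
#' @param subs list of subnetworks (from [filter_subnetworks()]).
#' @param sets a `GeneSetCollection`.
#' @param background character vector: the background universe (dataset genes
#'   that carry at least one pathway annotation).
#' @param threshold adjusted-p cut-off; values strictly greater are
#'   discarded. Default 0.2.
#' @return named numeric vector, pathway ID -> best adjusted p. Empty when
#'   nothing is enriched.
#' @export
enrich_subnetworks <- function(subs, sets, background, threshold = 0.2) {
  best <- numeric(0)
  if (length(subs) == 0) return(best)
  eff_sets <- lapply(sets$sets, intersect, background)
  eff_sizes <- lengths(eff_sets)
  bg <- length(background)
  for (sub in subs) {
    query <- intersect(sub$genes, background)
    q <- length(query)
    if (q == 0) next
    overlaps <- vapply(eff_sets, function(g) length(intersect(g, query)),
                       numeric(1))
    test <- overlaps >= 1
    if (!any(test)) next
    p <- mapply(hypergeom_test, overlaps[test], eff_sizes[test],
                MoreArgs = list(query_size = q, background = bg))
    adj <- bh_adjust(p)
    keep <- adj <= threshold
    for (id in names(adj)[keep]) {
      if (is.null(best[id]) || is.na(best[id]) || adj[[id]] < best[[id]]) {
        best[id] <- adj[[id]]
      }
    }
  }
  best
}

#' Repeated active-subnetwork enrichment
#'
#' Runs `cfg$iterations` rounds of greedy subnetwork search (each round
#' visits the seeds in a freshly shuffled order, so rounds explore different
#' locally maximal modules), filtering, and subnetwork enrichment; per
#' pathway it aggregates the lowest and highest adjusted p over the rounds
#' and counts the rounds in which the pathway was significant.
#'
#' @param pin an igraph PIN.
#' @param stats data frame from [t_test_genes()] (training samples only).
#' @param sets a `GeneSetCollection`.
#' @param cfg a [subnetwork_config()].
#' @param enrich_threshold adjusted-p cut-off, default 0.2.
#' @return data frame sorted by `lowest_adj_p` (ties by pathway ID) with
#'   columns `pathway_id`, `lowest_adj_p`, `highest_adj_p`, `occurrences`,
#'   and a list-column `member_genes` (significant input genes in the
#'   pathway). Zero rows when no pathway is ever enriched.
#' @export
run_enrichment <- function(pin, stats, sets, cfg = subnetwork_config(),
                           enrich_threshold = 0.2) {
  sig <- significant_genes(stats, cfg$p_threshold)
  background <- intersect(stats$gene, unique(unlist(sets$sets, use.names = FALSE)))
  sig_on_pin <- intersect(sig, igraph::V(pin)$name)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(cfg$iterations)) {
    it_seed <- derive_seed(cfg$seed, i)
    order_i <- if (length(sig_on_pin) > 0) {
      with_seed(it_seed, sample(sig_on_pin))
    } else NULL
    subs <- suppressWarnings(
      greedy_subnetworks(pin, stats, cfg, seed_order = order_i))
    subs <- suppressWarnings(
      filter_subnetworks(subs, cfg, n_sig_total = length(sig_on_pin)))
    hits <- enrich_subnetworks(subs, sets, background, enrich_threshold)
    for (id in names(hits)) {
      cur <- if (exists(id, envir = acc)) get(id, envir = acc) else
        c(lo = Inf, hi = -Inf, n = 0)
      assign(id, c(lo = min(cur[["lo"]], hits[[id]]),
                   hi = max(cur[["hi"]], hits[[id]]),
                   n = cur[["n"]] + 1), envir = acc)
    }
  }
  ids <- ls(acc)
  if (length(ids) == 0) {
    warning("no pathway enriched in any iteration")
    return(data.frame(pathway_id = character(0), lowest_adj_p = numeric(0),
                      highest_adj_p = numeric(0), occurrences = integer(0),
                      member_genes = I(list())))
  }
  rows <- t(vapply(ids, function(id) get(id, envir = acc), numeric(3)))
  out <- data.frame(pathway_id = ids,
                    lowest_adj_p = unname(rows[, "lo"]),
                    highest_adj_p = unname(rows[, "hi"]),
                    occurrences = as.integer(rows[, "n"]),
                    stringsAsFactors = FALSE)
  out$member_genes <- I(lapply(ids, function(id) {
    sort(intersect(sig, sets$sets[[id]]))
  }))
  out <- out[order(out$lowest_adj_p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enriched-pathway table
#'
#' Three-column TSV: `ID<TAB>p-value<TAB>PathWay Genes`, where `p-value` is
#' the lowest adjusted p over iterations and the gene column is comma-joined.
#'
#' @param enriched data frame from [run_enrichment()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_enrichment <- function(enriched, path) {
  out <- data.frame(
    ID = enriched$pathway_id,
    `p-value` = enriched$lowest_adj_p,
    `PathWay Genes` = vapply(enriched$member_genes, paste, character(1),
                             collapse = ", "),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
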