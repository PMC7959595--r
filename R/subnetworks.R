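# Greedy active-subnetwork search. An active subnetwork is a connected set
# of genes in the PIN consisting predominantly of significantly altered
# genes. Each member gene contributes z = qnorm(1 - p); a subnetwork of k
# genes scores sum(z) / sqrt(k), the standard aggregate-z module score, so a
# module of uniformly significant genes scores higher than a larger module
# diluted with null genes. Expansion looks up to max_depth hops away and
# pulls in the connecting genes, so a significant gene reachable through a
# non-significant linker can still be absorbed -- the defining ability of
# active-module search.

#' Configuration for the active-subnetwork search
#'
#' @param p_threshold seed significance threshold (inclusive), default 0.2.
#' @param max_depth expansion radius: candidate genes may lie up to this
#'   many hops from the current member set and are added together with the
#'   genes of a shortest connecting path. Default 2, which lets a module
#'   absorb a significant gene sitting behind one non-significant linker.
#' @param max_size cap on subnetwork size, default 25.
#' @param score_quantile keep subnetworks scoring at or above this empirical
#'   quantile of all subnetwork scores, default 0.80.
#' @param min_sig_frac minimum fraction of all significant genes a subnetwork
#'   must contain to survive filtering, default 0.02.
#' @param iterations number of independent search+enrichment iterations,
#'   default 10.
#' @param seed master seed for the iteration-level shuffling.
#' @return a `SubnetworkSearchConfig` list.
#' @export
subnetwork_config <- function(p_threshold = 0.2, max_depth = 2, max_size = 25,
                              score_quantile = 0.80, min_sig_frac = 0.02,
                              iterations = 10, seed = 1) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            max_depth >= 1, max_size >= 1,
            score_quantile >= 0, score_quantile <= 1,
            min_sig_frac >= 0, min_sig_frac <= 1,
            iterations >= 1)
  structure(list(p_threshold = p_threshold, max_depth = max_depth,
                 max_size = max_size, score_quantile = score_quantile,
                 min_sig_frac = min_sig_frac, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "SubnetworkSearchConfig")
}

#' Significance z-value of a gene
#'
#' Maps a p-value to the upper-tail standard-normal quantile,
#' `qnorm(1 - p)`; p is clamped to `[1e-15, 1 - 1e-15]` so the transform
#' stays finite.
#'
#' @param p p-value(s) in (0, 1); vectorized.
#' @return numeric z-value(s).
#' @export
gene_z <- function(p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Aggregate score of a gene set
#'
#' `sum(z) / sqrt(k)` over the member genes' z-values; under the null this is
#' approximately standard normal for any k, which makes module sizes
#' comparable.
#'
#' @param genes non-empty character vector of member genes.
#' @param stats data frame from [t_test_genes()] covering all `genes`.
#' @return the score, a single numeric.
#' @export
score_subnetwork <- function(genes, stats) {
  if (length(genes) == 0) stop("cannot score an empty subnetwork")
  p <- stats$p_value[match(genes, stats$gene)]
  if (anyNA(p)) stop("gene(s) missing from stats or with NaN p: ",
                     paste(genes[is.na(p)], collapse = ", "))
  sum(gene_z(p)) / sqrt(length(genes))
}

#' Greedy active-subnetwork search
#'
#' Seeds are the significant genes present in the PIN, visited in ascending
#' p-value order (ties broken lexicographically) unless `seed_order` is
#' given. From each unused seed the subnetwork grows by repeatedly making
#' the single score-maximizing addition, where an addition is an eligible
#' gene within `max_depth` hops of the current set together with the genes
#' of a shortest connecting path (so the module stays connected); eligible
#' means carrying a defined z and not yet claimed by an earlier subnetwork.
#' Growth stops when no addition strictly increases the score, or at
#' `max_size`. Genes claimed by a subnetwork are not reused, so the
#' returned modules are disjoint.
#'
#' @param pin an igraph PIN from [read_pin()].
#' @param stats data frame from [t_test_genes()].
#' @param cfg a [subnetwork_config()].
#' @param seed_order optional explicit ordering of seed genes (a permutation
#'   of the significant genes on the PIN); used by [run_enrichment()] to make
#'   iterations differ.
#' @return list of subnetworks sorted by score descending; each is a list
#'   with `genes`, `score`, `n_significant`.
#' @export
greedy_subnetworks <- function(pin, stats, cfg = subnetwork_config(),
                               seed_order = NULL) {
  ok <- !is.na(stats$p_value)
  pvals <- stats::setNames(stats$p_value[ok], stats$gene[ok])
  on_pin <- intersect(names(pvals), igraph::V(pin)$name)
  pvals <- pvals[on_pin]
  zvals <- gene_z(pvals)
  sig <- names(pvals)[pvals <= cfg$p_threshold]
  if (length(sig) == 0) {
    warning("no significant gene maps onto the PIN; no subnetworks")
    return(list())
  }
  if (is.null(seed_order)) {
    seeds <- sig[order(pvals[sig], sig)]
  } else {
    stopifnot(setequal(seed_order, sig))
    seeds <- seed_order
  }

  adj <- lapply(igraph::adjacent_vertices(pin, igraph::V(pin)), names)
  names(adj) <- igraph::V(pin)$name

  # multi-source BFS over eligible genes: returns for every reachable
  # eligible gene within max_depth hops the addition set (the gene plus the
  # intermediates of a shortest path back to `members`)
  additions <- function(members, used) {
    parent <- character(0)
    dist <- stats::setNames(rep(0L, length(members)), members)
    frontier <- sort(members)
    found <- character(0)
    for (d in seq_len(cfg$max_depth)) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in sort(adj[[u]])) {
          if (!is.na(dist[v])) next
          if (v %in% used || !v %in% names(zvals)) next
          dist[v] <- d
          parent[v] <- u
          nxt <- c(nxt, v)
        }
      }
      found <- c(found, nxt)
      if (length(nxt) == 0) break
      frontier <- nxt
    }
    lapply(stats::setNames(found, found), function(v) {
      path <- v
      while (!parent[[v]] %in% members) {
        v <- parent[[v]]
        path <- c(path, v)
      }
      path
    })
  }

  used <- character(0)
  subs <- list()
  for (s in seeds) {
    if (s %in% used) next
    members <- s
    score <- zvals[[s]]  # sum(z)/sqrt(1)
    zsum <- zvals[[s]]
    repeat {
      if (length(members) >= cfg$max_size) break
      adds <- additions(members, used)
      adds <- adds[lengths(adds) + length(members) <= cfg$max_size]
      if (length(adds) == 0) break
      new_scores <- vapply(adds, function(a) {
        (zsum + sum(zvals[a])) / sqrt(length(members) + length(a))
      }, numeric(1))
      best <- max(new_scores)
      if (best <= score) break
      tied <- adds[new_scores == best]
      sig <- vapply(tied, function(a) paste(sort(a), collapse = ","),
                    character(1))
      pick <- tied[[order(sig)[1]]]
      members <- c(members, pick)
      zsum <- zsum + sum(zvals[pick])
      score <- best
    }
    used <- c(used, members)
    subs[[length(subs) + 1L]] <- list(
      genes = members,
      score = unname(score),
      n_significant = sum(pvals[members] <= cfg$p_threshold)
    )
  }
  ord <- order(-vapply(subs, `[[`, numeric(1), "score"),
               vapply(subs, function(s) paste(sort(s$genes), collapse = ","),
                      character(1)))
  subs[ord]
}

#' Filter subnetworks on score and significant-gene content
#'
#' Keeps subnetworks whose score reaches the `score_quantile` empirical
#' quantile of all scores and which contain at least
#' `ceiling(min_sig_frac * n_sig_total)` significant genes. Input order is
#' preserved.
#'
#' @param subs list of subnetworks from [greedy_subnetworks()] (sorted by
#'   score descending).
#' @param cfg a [subnetwork_config()].
#' @param n_sig_total total number of significant genes (on the PIN).
#' @return the filtered list.
#' @export
filter_subnetworks <- function(subs, cfg, n_sig_total) {
  if (length(subs) == 0) return(subs)
  scores <- vapply(subs, `[[`, numeric(1), "score")
  thr <- stats::quantile(scores, cfg$score_quantile, names = FALSE)
  min_sig <- ceiling(cfg$min_sig_frac * n_sig_total)
  keep <- scores >= thr &
    vapply(subs, `[[`, numeric(1), "n_significant") >= min_sig
  out <- subs[keep]
  if (length(out) == 0) warning("all subnetworks removed by filtering")
  out
}
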