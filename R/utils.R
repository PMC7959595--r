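# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, then restores the caller's RNG state, so
#' library functions stay deterministic without clobbering the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic mixing kept below 2^31 so results stay valid R integers.
#' @keywords internal
#' @noRd
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 1009 + 12345) %%
               2147483647)
}

#' Stratified train/test split of sample indices
#'
#' Per-class training counts are `round(frac * n_class)` clamped to
#' `[1, n_class - 1]`, so both partitions always contain both classes.
#'
#' @param labels character/factor vector of class labels.
#' @param frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @keywords internal
#' @noRd
stratified_split <- function(labels, frac, seed) {
  stopifnot(frac > 0, frac < 1)
  labels <- as.character(labels)
  train <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, as.integer(round(frac * length(idx)))))
      train <- c(train, sort(sample(idx, n_tr)))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
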