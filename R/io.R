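# Readers and writers for expression matrices, labels, GMT gene sets and
# protein-interaction edge lists. All gene symbols are uppercased on input so
# that matching between dataset, pathway collection and network is by exact
# string equality, independent of input case.

#' Construct a validated two-class expression dataset
#'
#' The container used throughout the pipeline: a samples x genes numeric
#' matrix with a binary class label per sample.
#'
#' @param values numeric matrix, samples in rows, genes in columns. Row names
#'   are sample IDs, column names gene symbols (uppercased here).
#' @param labels character vector of per-sample class labels, one of exactly
#'   two values, in the same order as `rownames(values)` (or named by sample).
#' @param positive label of the positive (disease) class. Default `"pos"`.
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `values` (matrix), `labels` (character, named by sample), `positive`
#'   and `negative` class labels.
#' @export
expression_dataset <- function(values, labels, positive = "pos") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and gene column names")
  }
  colnames(values) <- toupper(colnames(values))
  if (anyDuplicated(colnames(values))) stop("duplicate gene IDs after uppercasing")
  if (anyDuplicated(rownames(values))) stop("duplicate sample IDs")
  if (!is.null(names(labels))) labels <- labels[rownames(values)]
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("`labels` length does not match the number of samples")
  }
  if (anyNA(labels)) stop("label missing for at least one sample")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("exactly two classes are required, found: ", paste(classes, collapse = ", "))
  }
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not among labels (", paste(classes, collapse = ", "), ")")
  }
  names(labels) <- rownames(values)
  structure(
    list(values = values, labels = labels,
         positive = positive, negative = setdiff(classes, positive)),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d genes (%s: %d, %s: %d)\n",
              nrow(x$values), ncol(x$values),
              x$positive, sum(x$labels == x$positive),
              x$negative, sum(x$labels == x$negative)))
  invisible(x)
}

#' Genes of a dataset
#' @param data an `ExpressionDataset`.
#' @return character vector of gene symbols.
#' @export
dataset_genes <- function(data) colnames(data$values)

#' Samples of a dataset
#' @param data an `ExpressionDataset`.
#' @return character vector of sample IDs.
#' @export
dataset_samples <- function(data) rownames(data$values)

#' Subset a dataset by sample index or ID
#' @param data an `ExpressionDataset`.
#' @param samples integer indices or sample IDs.
#' @return an `ExpressionDataset` restricted to those samples.
#' @export
subset_samples <- function(data, samples) {
  expression_dataset(data$values[samples, , drop = FALSE],
                     data$labels[samples], positive = data$positive)
}

#' Read an expression matrix and its label table
#'
#' The matrix TSV has a header row of sample IDs and gene symbols in the
#' first column (genes-in-rows contract; use `transpose = TRUE` for the other
#' layout). The label TSV has two columns, `sample_id<TAB>class`, and must
#' cover every sample.
#'
#' Duplicate gene rows collapse to the first occurrence with a warning.
#' Rows containing missing values are rejected (hard error), as are
#' non-numeric cells.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the 2-column label TSV.
#' @param positive positive class label (default `"pos"`).
#' @param transpose set `TRUE` when samples are in rows.
#' @return an `ExpressionDataset`.
#' @export
read_expression <- function(matrix_path, labels_path, positive = "pos",
                            transpose = FALSE) {
  tab <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- toupper(tab[[1]])
  raw <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  bad <- which(is.na(num) & !is.na(raw) & raw != "" & toupper(raw) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 raw[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(raw)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    miss <- unique(ids[which(is.na(num), arr.ind = TRUE)[, 1]])
    stop("missing values in rows: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicated gene ID(s) collapsed to first occurrence: ",
            paste(utils::head(unique(ids[dup]), 5), collapse = ", "))
    num <- num[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  mat <- t(num)  # to samples x genes

  lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                           col.names = c("sample_id", "class"),
                           colClasses = "character", quote = "",
                           comment.char = "")
  # tolerate an optional header line
  if (nrow(lab) > 0 && !lab$sample_id[1] %in% rownames(mat) &&
      tolower(lab$sample_id[1]) %in% c("sample", "sample_id", "id")) {
    lab <- lab[-1, , drop = FALSE]
  }
  labels <- stats::setNames(lab$class, lab$sample_id)
  absent <- setdiff(rownames(mat), names(labels))
  if (length(absent) > 0) {
    stop("sample(s) missing from label file: ", paste(absent, collapse = ", "))
  }
  out <- expression_dataset(mat, labels[rownames(mat)], positive = positive)
  if (min(table(out$labels)) < 2L) stop("fewer than 2 samples in one class")
  out
}

#' Write an expression dataset back to matrix + label TSVs
#'
#' Inverse of [read_expression()]: values round-trip at full precision and the
#' gene/sample ordering is preserved.
#'
#' @param data an `ExpressionDataset`.
#' @param matrix_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(data, matrix_path, labels_path) {
  mat <- t(data$values)  # genes back in rows
  df <- data.frame(Gene = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(data$labels),
                                class = unname(data$labels)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, labels_path))
}

#' Read a GMT gene-set collection
#'
#' One set per line: `ID<TAB>description<TAB>member1<TAB>member2...`.
#' Member symbols are uppercased; sets with no members are dropped with a
#' warning; duplicate IDs are an error.
#'
#' @param path path to the GMT file.
#' @return a `GeneSetCollection`: list with `sets` (named list of character
#'   vectors, names are pathway IDs) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); desc <- character(0); sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("unreadable GMT line ", i, ": fewer than 2 fields")
    members <- unique(toupper(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("gene set '", parts[1], "' (line ", i, ") has no members; dropped")
      next
    }
    if (parts[1] %in% ids) stop("duplicate pathway ID '", parts[1], "' at line ", i)
    ids <- c(ids, parts[1]); desc <- c(desc, parts[2])
    sets[[parts[1]]] <- members
  }
  structure(list(sets = sets, descriptions = stats::setNames(desc, ids)),
            class = "GeneSetCollection")
}

#' Write a gene-set collection to GMT
#' @param sets a `GeneSetCollection`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets$sets), function(id) {
    paste(c(id, unname(sets$descriptions[id]), sets$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("GeneSetCollection: %d sets, %d distinct genes (sizes %d-%d)\n",
              length(x$sets), length(unique(unlist(x$sets))),
              min(sizes), max(sizes)))
  invisible(x)
}

#' Read a protein-interaction network edge list
#'
#' Accepts a 2-column whitespace/tab-delimited edge list or a 3-column SIF
#' (interaction type in the middle column, ignored). The graph is undirected
#' and simple: self-loops and duplicate edges are removed, with counts
#' reported. Symbols are uppercased.
#'
#' @param path path to the edge-list file.
#' @return an undirected simple [igraph::igraph] graph whose vertex names are
#'   gene symbols.
#' @export
read_pin <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      quote = "", comment.char = ""),
    error = function(e) stop("empty or unreadable PIN file: ", path))
  if (nrow(tab) == 0) stop("empty PIN file: ", path)
  if (ncol(tab) == 3) tab <- tab[, c(1, 3)]
  if (ncol(tab) != 2) stop("PIN file must have 2 columns (or 3-column SIF)")
  from <- toupper(tab[[1]]); to <- toupper(tab[[2]])
  loops <- from == to
  keep <- !loops
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]), directed = FALSE)
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- n_before - igraph::ecount(g)
  if (sum(loops) > 0 || n_dup > 0) {
    message(sprintf("read_pin: removed %d self-loop(s) and %d duplicate edge(s)",
                    sum(loops), n_dup))
  }
  g
}
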