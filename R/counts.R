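#' Validate and coerce a taxa count table
#'
#' Community profiles are handled internally as an N x S matrix of
#' non-negative integer counts with samples as rows and taxa (genera, OTUs)
#' as columns. `as_count_matrix()` accepts either such a matrix or a data
#' frame whose first column holds sample identifiers and whose remaining
#' columns hold counts, and checks the invariants the model relies on:
#' integral non-negative entries, unique sample identifiers and unique taxon
#' names.
#'
#' Samples with zero total counts are mathematically valid (their marginal
#' evidence is 1) but carry no information, so they are kept with a warning.
#'
#' @param x A data frame (first column sample IDs, remaining columns counts)
#'   or a numeric matrix with sample IDs as row names.
#' @param taxa_as_rows If `TRUE`, `x` is transposed first (taxa-as-rows
#'   exports are common in amplicon pipelines).
#' @return A numeric matrix of counts with `sample_id` row names and taxon
#'   column names.
#' @examples
#' tb <- tibble::tibble(sample_id = c("a", "b"), Bacteroides = c(5L, 0L),
#'                      Prevotella = c(1L, 9L))
#' as_count_matrix(tb)
#' @export
as_count_matrix <- function(x, taxa_as_rows = FALSE) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("count table needs an ID column plus at least one taxon column")
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      ids <- as.character(first)
      m <- as.matrix(x[, -1, drop = FALSE])
      rownames(m) <- ids
    } else {
      m <- as.matrix(x)
      if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
    }
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  } else {
    stop("`x` must be a data frame or matrix of counts")
  }
  if (taxa_as_rows) m <- t(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  if (nrow(m) < 1 || ncol(m) < 1) stop("count matrix must have at least one sample and one taxon")

  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: sample '%s', taxon '%s' (value %s)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], format(m[bad[1, 1], bad[1, 2]])
    ))
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample IDs: ", paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate taxon names: ", paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning("sample(s) with zero total counts: ", paste(rownames(m)[zero], collapse = ", "))
  }
  m
}

#' Convert a count matrix back to a tibble
#'
#' @param m A count matrix as returned by [as_count_matrix()].
#' @return A tibble with a `sample_id` column followed by one column per taxon.
#' @export
count_tbl <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  ))
}
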