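#' Read a taxa count table from delimited text or BIOM
#'
#' TSV is the canonical dialect; comma-delimited files are accepted by
#' sniffing the header line. The first column must hold sample identifiers
#' (or taxon names with `taxa_as_rows = TRUE`, the orientation common in
#' amplicon-pipeline exports). Files ending in `.biom` are read with the
#' biomformat package when it is installed.
#'
#' @param path Path to the table.
#' @param taxa_as_rows The file stores taxa as rows; the matrix is
#'   transposed after reading.
#' @return A validated count matrix (see [as_count_matrix()]).
#' @export
read_counts <- function(path, taxa_as_rows = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples in BIOM
    return(as_count_matrix(t(m), taxa_as_rows = taxa_as_rows))
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_count_matrix(as.data.frame(df), taxa_as_rows = taxa_as_rows)
}

#' Write a count matrix as TSV
#'
#' @param x A count table accepted by [as_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  m <- as_count_matrix(x)
  readr::write_tsv(count_tbl(m), path, progress = FALSE)
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Write a fitted DMM to a schema-versioned JSON model file
#'
#' Stores the mixture parameters (lambda, alpha, theta, mean, weights),
#' hyperprior, fit metadata (seed, tolerances, lower-bound trace, the
#' multinomial-coefficient and Hessian conventions) and, when supplied, the
#' negative Laplace log evidence. Values are written at full precision so
#' the file round-trips through [read_dmm_model()] bitwise.
#'
#' @param fit A [dmm_fit()].
#' @param path Output path.
#' @param laplace Optional [laplace_evidence()] result to embed.
#' @return `path`, invisibly.
#' @export
write_dmm_model <- function(fit, path, laplace = NULL) {
  stopifnot(inherits(fit, "dmm_fit"))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    k = fit$model$k,
    taxa = fit$model$taxa,
    weights = fit$model$weights,
    lambda = asplit_rows(fit$model$lambda),
    alpha = asplit_rows(fit$model$alpha),
    theta = fit$model$theta,
    mean = asplit_rows(fit$model$mean),
    hyperprior = list(eta = fit$control$eta, nu = fit$control$nu),
    fit = list(
      seed = fit$control$seed,
      em_tol = fit$control$em_tol,
      grad_tol = fit$control$grad_tol,
      restarts = fit$control$restarts,
      init = fit$control$init,
      include_coefficient = fit$control$include_coefficient,
      weight_block = fit$control$weight_block,
      converged = fit$converged,
      n_iter = fit$n_iter,
      neg_log_posterior = fit$neg_log_posterior,
      lower_bound_trace = fit$trace
    )
  )
  if (!is.null(laplace)) {
    doc$laplace <- list(
      neg_laplace_log_evidence = laplace$neg_laplace_log_evidence,
      P = laplace$P,
      log_det_hessian = laplace$log_det_hessian,
      hessian_condition_ok = laplace$hessian_condition_ok
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

asplit_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))

# inverse of asplit_rows after jsonlite simplification (list of rows for
# ragged input, matrix for rectangular, plain vector for a single row)
rows_to_matrix <- function(x, k) {
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), nrow = k, byrow = TRUE)
}

#' Read a DMM model file
#'
#' @param path Path to a JSON file written by [write_dmm_model()].
#' @return A list with `model` (a [dmm_model()]), `hyperprior`, `fit`
#'   metadata and, if present, `laplace`.
#' @export
read_dmm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) stop("not a dmmix model file: ", path)
  alpha <- rows_to_matrix(doc$alpha, doc$k)
  colnames(alpha) <- doc$taxa
  model <- dmm_model(alpha, weights = as.numeric(doc$weights))
  list(model = model, hyperprior = doc$hyperprior, fit = doc$fit,
       laplace = doc$laplace, schema_version = doc$schema_version)
}

#' Read per-sample class labels
#'
#' Two-column delimited text (sample ID, label), with or without a header.
#'
#' @param path Path to the label file.
#' @return A named character vector (sample ID -> label).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = delim, header = FALSE,
                          colClasses = "character")
  if (tolower(df[1, 1]) %in% c("sample_id", "sample", "id")) df <- df[-1, , drop = FALSE]
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}
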