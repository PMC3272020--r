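#' Hard cluster assignment by maximum posterior responsibility
#'
#' Each sample is imputed to the metacommunity with the highest posterior
#' membership probability; ties break toward the lowest component index.
#'
#' @param fit A [dmm_fit()].
#' @return A tibble with columns `sample_id`, `cluster` and `posterior`
#'   (the winning responsibility).
#' @export
hard_assign <- function(fit) {
  stopifnot(inherits(fit, "dmm_fit"))
  z <- fit$responsibilities
  lab <- max.col(z, ties.method = "first")
  tibble::tibble(
    sample_id = rownames(z),
    cluster = as.integer(lab),
    posterior = z[cbind(seq_len(nrow(z)), lab)]
  )
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' For relative-abundance (simplex) inputs this is `1 - sum(pmin(u, v))`;
#' the general form `1 - 2*sum(pmin(u, v)) / (sum(u) + sum(v))` is used so
#' unnormalised non-negative profiles are also accepted.
#'
#' @param u,v Non-negative abundance vectors of equal length.
#' @return A dissimilarity in `[0, 1]` (0 identical, 1 disjoint support).
#' @examples
#' bray_curtis(c(0.7, 0.3), c(0.3, 0.7)) # 0.4
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("profiles differ in length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative")
  1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))
}

#' Difference of mixture components to a reference metacommunity
#'
#' Quantifies how far each fitted component lies from a reference component
#' (typically the single-component fit to the same data): for component k,
#' `d_k = 100 * sum_j |m_kj - m_ref_j|`, a quantity between 0% (identical)
#' and 200% (completely dissimilar). Per-taxon contributions
#' `c_j = 100 * sum_k |m_kj - m_ref_j|` are ranked so the taxa driving the
#' difference head the table.
#'
#' @param components A [dmm_fit()], [dmm_model()], or K x S matrix of
#'   component mean compositions.
#' @param reference A [dmm_fit()], [dmm_model()] (first component used), or
#'   an S-simplex mean vector.
#' @return An object of class `dmm_difference` with `per_taxon` (tibble:
#'   `taxon`, `reference_pct`, one `compK_pct` column per component,
#'   `difference_pct`, `cumulative_pct` of the grand total),
#'   `per_component` (tibble: `component`, `total_pct`) and `grand_total`.
#' @export
difference_to_reference <- function(components, reference) {
  M <- component_means_of(components)
  r <- reference_mean_of(reference)
  if (ncol(M) != length(r)) stop("component and reference taxon dimensions differ")
  D <- abs(sweep(M, 2, r))
  d_k <- 100 * rowSums(D)
  c_j <- 100 * colSums(D)
  grand <- sum(d_k)
  ord <- order(c_j, decreasing = TRUE)
  comp_cols <- as.data.frame(100 * t(M[, ord, drop = FALSE]))
  names(comp_cols) <- paste0("comp", seq_len(nrow(M)), "_pct")
  per_taxon <- tibble::as_tibble(cbind(
    tibble::tibble(taxon = colnames(M)[ord], reference_pct = 100 * r[ord]),
    comp_cols,
    tibble::tibble(
      difference_pct = c_j[ord],
      cumulative_pct = if (grand > 0) 100 * cumsum(c_j[ord]) / grand else cumsum(c_j[ord])
    )
  ))
  structure(
    list(per_taxon = per_taxon,
         per_component = tibble::tibble(component = seq_along(d_k), total_pct = d_k),
         grand_total = grand),
    class = "dmm_difference"
  )
}

component_means_of <- function(x) {
  if (inherits(x, "dmm_fit")) return(x$model$mean)
  if (inherits(x, "dmm_model")) return(x$mean)
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("taxon", seq_len(ncol(x)))
    return(x)
  }
  m <- matrix(x, nrow = 1)
  colnames(m) <- names(x) %||% paste0("taxon", seq_along(x))
  m
}

reference_mean_of <- function(x) {
  m <- component_means_of(x)
  if (nrow(m) > 1) warning("reference has several components; using the first")
  drop(m[1, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dmm_difference <- function(x, n = 10, ...) {
  cat(sprintf("Difference to reference: grand total %.1f%% (per component: %s)\n",
              x$grand_total, paste(sprintf("%.1f%%", x$per_component$total_pct), collapse = ", ")))
  print(head(x$per_taxon, n))
  invisible(x)
}

#' Match two sets of metacommunity components by Bray-Curtis distance
#'
#' Maps each component of set A onto its closest partner in set B. When
#' `|A| <= |B|` the matching is greedy one-to-one (globally smallest
#' distance assigned first); otherwise each A component simply takes its
#' nearest B partner. The full distance matrix is always attached so the
#' matching can be audited.
#'
#' @param means_a,means_b Matrices of component mean compositions (rows =
#'   components), or [dmm_fit()]/[dmm_model()] objects.
#' @return A tibble with columns `a`, `b` and `distance`; the Bray-Curtis
#'   matrix is in `attr(, "distance_matrix")`.
#' @export
match_components <- function(means_a, means_b) {
  A <- component_means_of(means_a)
  B <- component_means_of(means_b)
  D <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) D[i, j] <- bray_curtis(A[i, ], B[j, ])
  map <- integer(nrow(A))
  if (nrow(A) <= nrow(B)) {
    Dw <- D
    for (step in seq_len(nrow(A))) {
      ij <- which(Dw == min(Dw), arr.ind = TRUE)[1, ]
      map[ij[1]] <- ij[2]
      Dw[ij[1], ] <- Inf
      Dw[, ij[2]] <- Inf
    }
  } else {
    map <- apply(D, 1, which.min)
  }
  out <- tibble::tibble(a = seq_len(nrow(A)), b = map,
                        distance = D[cbind(seq_len(nrow(A)), map)])
  attr(out, "distance_matrix") <- D
  out
}

#' Cross-tabulate cluster assignments against sample categories
#'
#' For each category (e.g. BMI class), the percentage of its samples
#' assigned to each metacommunity cluster; rows sum to 100%.
#'
#' @param assignment A tibble from [hard_assign()] (or a vector of cluster
#'   labels named by sample ID).
#' @param labels A named vector (sample ID -> category) or a two-column data
#'   frame (`sample_id`, category).
#' @return A tibble with one row per category, a `label` column, one
#'   `cluster_<k>` column per cluster (percentages) and an `n` column.
#' @export
cross_tabulate <- function(assignment, labels) {
  if (is.data.frame(assignment)) {
    cl <- setNames(assignment$cluster, assignment$sample_id)
  } else {
    cl <- assignment
  }
  if (is.data.frame(labels)) labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  unknown <- setdiff(names(labels), names(cl))
  if (length(unknown)) stop("labels refer to unknown sample IDs: ", paste(unknown, collapse = ", "))
  ids <- names(labels)
  tab <- table(label = labels[ids], cluster = cl[ids])
  pct <- 100 * prop.table(tab, margin = 1)
  out <- tibble::as_tibble(as.data.frame.matrix(pct), rownames = "label")
  names(out)[-1] <- paste0("cluster_", colnames(tab))
  out$n <- as.integer(rowSums(tab))
  out
}
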