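#' Construct a Dirichlet mixture model
#'
#' A mixture of K Dirichlet "metacommunity" components over S taxa. Each
#' component is parameterised by a positive vector `alpha[k, ]`; its sum
#' `theta` acts like a precision (large theta concentrates communities near
#' the component mean `alpha/theta`, small theta disperses them) and the
#' normalised vector is the expected community composition. Internally the
#' components are stored on the unconstrained log scale `lambda = log(alpha)`
#' used during optimisation.
#'
#' @param alpha K x S matrix of positive Dirichlet parameters (a single
#'   numeric vector is treated as one component).
#' @param weights Mixture weights, length K, non-negative; normalised to sum
#'   to one.
#' @return An object of class `dmm_model` with elements `alpha`, `lambda`,
#'   `weights`, `theta` (per-component precision) and `mean` (K x S matrix of
#'   component mean compositions).
#' @examples
#' dmm_model(rbind(c(10, 1, 1), c(1, 1, 10)), weights = c(0.7, 0.3))
#' @export
dmm_model <- function(alpha, weights = NULL) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = 1, dimnames = list(NULL, names(alpha)))
  if (!is.matrix(alpha) || !is.numeric(alpha)) stop("`alpha` must be a numeric matrix")
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("all Dirichlet parameters must be finite and > 0")
  k <- nrow(alpha)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stop("`weights` must have one entry per component")
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative with positive sum")
  }
  if (is.null(colnames(alpha))) colnames(alpha) <- paste0("taxon", seq_len(ncol(alpha)))
  theta <- rowSums(alpha)
  structure(
    list(
      alpha = alpha,
      lambda = log(alpha),
      weights = weights / sum(weights),
      theta = theta,
      mean = alpha / theta,
      k = k,
      s = ncol(alpha),
      taxa = colnames(alpha)
    ),
    class = "dmm_model"
  )
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf("Dirichlet mixture model: %d component(s), %d taxa\n", x$k, x$s))
  cat("weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  cat("theta:  ", paste(signif(x$theta, 4), collapse = " "), "\n")
  invisible(x)
}

#' Log multinomial Beta function
#'
#' `B(alpha) = prod(Gamma(alpha_j)) / Gamma(sum(alpha))`, the normalising
#' constant of the Dirichlet distribution, computed entirely in log space.
#'
#' @param alpha Vector of positive Dirichlet parameters.
#' @return `log B(alpha)` as a single number.
#' @examples
#' log_multinomial_beta(c(1, 1, 1)) # log(1/2)
#' @export
log_multinomial_beta <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) < 1) stop("`alpha` must be a numeric vector")
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("all entries of `alpha` must be finite and > 0")
  sum(lgamma(alpha)) - lgamma(sum(alpha))
}

# log J! / prod(x_j!) for one count vector
log_multinomial_coeff <- function(x) {
  lgamma(sum(x) + 1) - sum(lgamma(x + 1))
}

#' Log marginal evidence of a sample under one Dirichlet component
#'
#' The probability of a count vector with the latent community composition
#' integrated out against a `Dirichlet(alpha)` prior. This has the closed
#' form `coeff * B(alpha + x) / B(alpha)` where `B` is the multinomial Beta
#' function and `coeff` the multinomial coefficient. The coefficient is
#' included by default so the evidence is a true probability over count
#' vectors; it is constant in `alpha`, so fits and model comparisons on
#' fixed data do not depend on the convention (hold it constant within any
#' comparison).
#'
#' @param x Non-negative integer count vector over the S taxa.
#' @param alpha Positive Dirichlet parameter vector of the same length.
#' @param include_coefficient Include the multinomial coefficient (default
#'   `TRUE`).
#' @return `log p(x | alpha)`.
#' @examples
#' exp(log_component_evidence(c(3, 2), c(1, 1))) # 1/6: uniform prior, J = 5
#' @export
log_component_evidence <- function(x, alpha, include_coefficient = TRUE) {
  if (length(x) != length(alpha)) {
    stop(sprintf("length mismatch: %d counts vs %d Dirichlet parameters", length(x), length(alpha)))
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("`x` must be a vector of non-negative integers")
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("all entries of `alpha` must be finite and > 0")
  j <- sum(x)
  theta <- sum(alpha)
  out <- sum(lgamma(alpha + x)) - lgamma(theta + j) - sum(lgamma(alpha)) + lgamma(theta)
  if (include_coefficient) out <- out + log_multinomial_coeff(x)
  out
}

# N x K matrix of per-sample, per-component log evidences (vectorised
# workhorse used by the E-step, the mixture evidence and the classifier)
log_evidence_matrix <- function(X, model, include_coefficient = TRUE) {
  if (ncol(X) != model$s) {
    stop(sprintf("count matrix has %d taxa but model has %d", ncol(X), model$s))
  }
  J <- rowSums(X)
  coeff <- if (include_coefficient) lgamma(J + 1) - rowSums(lgamma(X + 1)) else 0
  out <- matrix(NA_real_, nrow(X), model$k)
  for (k in seq_len(model$k)) {
    a <- model$alpha[k, ]
    th <- model$theta[k]
    out[, k] <- rowSums(lgamma(sweep(X, 2, a, "+"))) - lgamma(th + J) -
      sum(lgamma(a)) + lgamma(th) + coeff
  }
  dimnames(out) <- list(rownames(X), NULL)
  out
}

#' Log evidence of a sample under a Dirichlet mixture
#'
#' `log sum_k pi_k p(x | alpha_k)`, evaluated with the log-sum-exp
#' stabilisation. The dataset-level log evidence is the sum of this quantity
#' over samples.
#'
#' @inheritParams log_component_evidence
#' @param model A [dmm_model()].
#' @return `log p(x | model)`.
#' @export
log_mixture_evidence <- function(x, model, include_coefficient = TRUE) {
  le <- log_evidence_matrix(matrix(x, nrow = 1), model, include_coefficient)
  lw <- ifelse(model$weights > 0, log(model$weights), -Inf)
  logsumexp(lw + drop(le))
}

#' Posterior of the community composition given a sample
#'
#' The Dirichlet is conjugate to the multinomial, and conjugacy is preserved
#' under mixing: given counts `x`, the posterior over the community vector is
#' again a Dirichlet mixture whose component k has parameters
#' `alpha_k + x` and whose weight is the posterior probability that the
#' sample derives from metacommunity k.
#'
#' @inheritParams log_mixture_evidence
#' @return A [dmm_model()] whose `weights` are the posterior membership
#'   probabilities and whose components are the updated Dirichlets.
#' @export
posterior_mixture <- function(x, model, include_coefficient = TRUE) {
  le <- drop(log_evidence_matrix(matrix(x, nrow = 1), model, include_coefficient))
  lw <- ifelse(model$weights > 0, log(model$weights), -Inf)
  lp <- lw + le
  w <- exp(lp - logsumexp(lp))
  dmm_model(sweep(model$alpha, 2, x, "+"), weights = w / sum(w))
}

#' Mean composition of a Dirichlet component
#'
#' @param alpha Positive Dirichlet parameter vector, or a [dmm_model()]
#'   (whose K x S matrix of component means is returned).
#' @return A probability vector `alpha / sum(alpha)` (or the K x S matrix of
#'   such vectors for a model).
#' @examples
#' component_mean(c(1, 2, 3))
#' @export
component_mean <- function(alpha) {
  if (inherits(alpha, "dmm_model")) return(alpha$mean)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("all entries of `alpha` must be finite and > 0")
  alpha / sum(alpha)
}
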