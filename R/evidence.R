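#' Analytic Hessian of the negative log posterior at the MPE
#'
#' Second derivatives of the negative expected log posterior at the
#' converged parameters, with responsibilities held frozen at their
#' converged values (the surface the EM maximised). The matrix is block
#' diagonal: one dense S x S block per component over `lambda = log(alpha)`
#' (digamma/trigamma terms plus the `nu * exp(lambda)` hyperprior diagonal)
#' and, when `weight_block` is on and K > 1, a (K-1) x (K-1) block for the
#' softmax-reparameterised mixture weights.
#'
#' @param fit A [dmm_fit()].
#' @param weight_block Include the mixture-weight block (defaults to the
#'   fit's control setting).
#' @return A symmetric P x P matrix with labelled rows/columns, where
#'   P = K*S (+ K-1 with the weight block).
#' @export
neg_log_posterior_hessian <- function(fit, weight_block = fit$control$weight_block) {
  stopifnot(inherits(fit, "dmm_fit"))
  if (!fit$converged) warning("fit did not converge; Hessian evaluated at the last iterate")
  X <- fit$counts
  J <- rowSums(X)
  z <- fit$responsibilities
  k <- fit$model$k
  s <- fit$model$s
  ctl <- fit$control
  p <- k * s + if (weight_block && k > 1) k - 1L else 0L
  H <- matrix(0, p, p)
  labels <- character(p)
  for (kk in seq_len(k)) {
    idx <- (kk - 1) * s + seq_len(s)
    Hk <- -component_hessian(fit$model$lambda[kk, ], X, z[, kk], J, ctl$eta, ctl$nu)
    if (any(!is.finite(Hk))) {
      bad <- which(!is.finite(Hk), arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite Hessian entry at component %d, taxa %s x %s",
                   kk, fit$model$taxa[bad[1]], fit$model$taxa[bad[2]]))
    }
    H[idx, idx] <- (Hk + t(Hk)) / 2
    labels[idx] <- paste0("comp", kk, ":", fit$model$taxa)
  }
  if (weight_block && k > 1) {
    idx <- k * s + seq_len(k - 1)
    pi_k <- fit$model$weights
    n <- nrow(X)
    # negative second derivative of sum_k n_k log pi_k under softmax
    # (component K's logit fixed at zero)
    W <- n * (diag(pi_k[-k], k - 1) - pi_k[-k] %o% pi_k[-k])
    H[idx, idx] <- (W + t(W)) / 2
    labels[idx] <- paste0("weight:comp", seq_len(k - 1))
  }
  dimnames(H) <- list(labels, labels)
  H
}

#' Laplace approximation of the model evidence
#'
#' Approximates the log model evidence by a Gaussian expansion at the
#' maximum posterior estimate: `log p(X|K) ~ log posterior(MPE) + (P/2) log
#' 2*pi - 0.5 log det H`. The negative is returned, so a better fit
#' corresponds to a smaller value; [select_k()] minimises it over K.
#' Near-singular Hessians are handled by flooring eigenvalues at 1e-10 and
#' flagging the result rather than failing.
#'
#' @inheritParams neg_log_posterior_hessian
#' @return An object of class `dmm_laplace`: `neg_laplace_log_evidence`,
#'   parameter count `P`, `log_det_hessian`, and `hessian_condition_ok`
#'   (`FALSE` when eigenvalues were floored or negative beyond tolerance).
#' @export
laplace_evidence <- function(fit, weight_block = fit$control$weight_block) {
  H <- neg_log_posterior_hessian(fit, weight_block)
  p <- nrow(H)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ok <- all(ev > 1e-10) && all(ev > -1e-6 * max(abs(ev)))
  ev_floored <- pmax(ev, 1e-10)
  log_det <- sum(log(ev_floored))
  log_post <- -fit$neg_log_posterior
  log_ev <- log_post + p / 2 * log(2 * pi) - log_det / 2
  structure(
    list(neg_laplace_log_evidence = -log_ev, P = p,
         log_det_hessian = log_det, hessian_condition_ok = ok,
         weight_block = weight_block && fit$model$k > 1),
    class = "dmm_laplace"
  )
}

#' @export
print.dmm_laplace <- function(x, ...) {
  cat(sprintf("Laplace model evidence: -log E = %.4f (P = %d parameters%s)\n",
              x$neg_laplace_log_evidence, x$P,
              if (!x$hessian_condition_ok) "; Hessian flagged near-singular" else ""))
  invisible(x)
}

#' Select the number of metacommunities by Laplace evidence
#'
#' Fits a DMM for each K in `k_range` and computes the negative Laplace log
#' evidence; the best K attains the minimum. This is the model-based
#' alternative to heuristic cluster-number indices: the evidence
#' automatically penalises the extra parameters of larger mixtures.
#'
#' @inheritParams dmm_fit
#' @param k_range Integer vector of candidate component counts.
#' @return An object of class `dmm_select`: a tibble `table` with columns
#'   `k`, `neg_evidence`, `P`, `converged`, `hessian_ok`; `best_k`;
#'   `best_fit`; and the full list of `fits` (named by K). Failed fits are
#'   recorded with `NA` evidence and skipped with a warning.
#' @examples
#' sim <- dmm_simulate(dmm_benchmark_spec("k1", seed = 1))
#' sel <- select_k(sim$counts, k_range = 1:2)
#' sel$best_k
#' @export
select_k <- function(counts, k_range = 1:5, control = dmm_control()) {
  X <- as_count_matrix(counts)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 1))
  rows <- list()
  fits <- list()
  for (k in k_range) {
    res <- tryCatch({
      fit <- dmm_fit(X, k, control)
      lap <- laplace_evidence(fit)
      list(fit = fit, lap = lap)
    }, error = function(e) {
      warning(sprintf("fit for K = %d failed and was skipped: %s", k, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        k = k, neg_evidence = NA_real_, P = NA_integer_,
        converged = NA, hessian_ok = NA)
      next
    }
    fits[[as.character(k)]] <- res$fit
    rows[[length(rows) + 1]] <- tibble::tibble(
      k = k, neg_evidence = res$lap$neg_laplace_log_evidence,
      P = res$lap$P, converged = res$fit$converged,
      hessian_ok = res$lap$hessian_condition_ok)
  }
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$neg_evidence))) stop("every candidate K failed to fit")
  best_k <- tab$k[which.min(tab$neg_evidence)]
  structure(
    list(table = tab, best_k = best_k,
         best_fit = fits[[as.character(best_k)]], fits = fits,
         control = control),
    class = "dmm_select"
  )
}

#' @export
print.dmm_select <- function(x, ...) {
  cat("DMM model selection by Laplace evidence\n")
  print(x$table)
  cat("best K:", x$best_k, "\n")
  invisible(x)
}

#' Credible intervals for component compositions from the inverse Hessian
#'
#' The diagonal of the inverse Hessian gives the posterior variance of each
#' `lambda_kj`; interval endpoints are the MPE plus/minus two standard
#' deviations on the lambda scale, mapped to the relative-abundance scale by
#' `exp(lambda +/- 2*sigma) / (exp(lambda +/- 2*sigma) + sum of the other
#' alphas)` and reported in percent.
#'
#' @inheritParams neg_log_posterior_hessian
#' @return A tibble with columns `component`, `taxon`, `lower`, `estimate`
#'   and `upper` (percent relative abundance). Parameters whose variance is
#'   unavailable (singular Hessian) get `NA` bounds.
#' @export
credible_intervals <- function(fit, weight_block = FALSE) {
  H <- neg_log_posterior_hessian(fit, weight_block = weight_block)
  k <- fit$model$k
  s <- fit$model$s
  vars <- rep(NA_real_, k * s)
  inv <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(inv)) vars <- diag(inv)[seq_len(k * s)]
  vars[!is.na(vars) & vars < 0] <- NA_real_
  sigma <- sqrt(vars)
  out <- vector("list", k)
  for (kk in seq_len(k)) {
    lam <- fit$model$lambda[kk, ]
    a <- fit$model$alpha[kk, ]
    rest <- fit$model$theta[kk] - a
    sg <- sigma[(kk - 1) * s + seq_len(s)]
    lo <- exp(lam - 2 * sg); hi <- exp(lam + 2 * sg)
    out[[kk]] <- tibble::tibble(
      component = kk,
      taxon = fit$model$taxa,
      lower = 100 * lo / (lo + rest),
      estimate = 100 * fit$model$mean[kk, ],
      upper = 100 * hi / (hi + rest)
    )
  }
  dplyr::bind_rows(out)
}
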