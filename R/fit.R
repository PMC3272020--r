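#' Control parameters for DMM fitting
#'
#' @param eta,nu Shape and rate of the i.i.d. Gamma hyperprior on every
#'   Dirichlet parameter `alpha_kj`. The defaults (0.1, 0.1) give a vague
#'   prior with mean 1 that keeps parameters for unobserved taxa finite.
#' @param max_iter Maximum number of EM cycles.
#' @param em_tol Relative change of the expected log posterior below which
#'   EM is declared converged.
#' @param grad_tol Sup-norm gradient tolerance for the per-component
#'   quasi-Newton M-step.
#' @param restarts Number of independent restarts; the fit with the best
#'   final objective is kept.
#' @param seed Integer seed controlling initialisation; fits are
#'   deterministic given the seed.
#' @param init Initialisation: `"kmeans"` (k-means with k-means++ seeding on
#'   relative abundances, hard initial assignments) or `"random_soft"`
#'   (responsibility rows drawn from a symmetric Dirichlet).
#' @param include_coefficient Include the multinomial coefficient in all
#'   reported evidences (constant in the parameters; see
#'   [log_component_evidence()]).
#' @param weight_block Include a (K-1)-parameter softmax block for the
#'   mixture weights in the Laplace Hessian (see [laplace_evidence()]).
#' @param optim_maxit Iteration cap for each BFGS M-step call.
#' @return A list of class `dmm_control`.
#' @export
dmm_control <- function(eta = 0.1, nu = 0.1, max_iter = 250, em_tol = 1e-6,
                        grad_tol = 1e-5, restarts = 3, seed = 1,
                        init = c("kmeans", "random_soft"),
                        include_coefficient = TRUE, weight_block = TRUE,
                        optim_maxit = 200) {
  init <- match.arg(init)
  stopifnot(eta > 0, nu > 0, max_iter >= 1, em_tol > 0, grad_tol > 0,
            restarts >= 1, optim_maxit >= 1)
  structure(
    list(eta = eta, nu = nu, max_iter = max_iter, em_tol = em_tol,
         grad_tol = grad_tol, restarts = restarts, seed = as.integer(seed),
         init = init, include_coefficient = include_coefficient,
         weight_block = weight_block, optim_maxit = optim_maxit),
    class = "dmm_control"
  )
}

#' Posterior responsibilities of samples for mixture components
#'
#' The E-step quantity: `z[i, k]` is the posterior probability that sample i
#' derives from metacommunity k, `pi_k p(x_i|alpha_k) / sum_l pi_l
#' p(x_i|alpha_l)`, evaluated via log-sum-exp.
#'
#' @param counts A count table accepted by [as_count_matrix()].
#' @param model A [dmm_model()].
#' @param include_coefficient Passed to the evidence computation (cancels in
#'   the ratio; kept for consistency).
#' @return An N x K matrix with rows summing to one.
#' @export
responsibilities <- function(counts, model, include_coefficient = TRUE) {
  X <- as_count_matrix(counts)
  e_step(X, model, include_coefficient)$z
}

# E-step: responsibilities plus per-sample log mixture evidence
e_step <- function(X, model, include_coefficient = TRUE) {
  le <- log_evidence_matrix(X, model, include_coefficient)
  lw <- ifelse(model$weights > 0, log(model$weights), -Inf)
  lp <- sweep(le, 2, lw, "+")
  m <- apply(lp, 1, max)
  z <- exp(lp - m)
  rs <- rowSums(z)
  list(z = z / rs, log_evidence = m + log(rs))
}

#' Log density of the Gamma hyperprior in log-parameter space
#'
#' Each `alpha_kj` carries an independent Gamma(eta, nu) hyperprior. After
#' the change of variables `lambda = log(alpha)` the log density of one
#' parameter is `eta*log(nu) - lgamma(eta) + eta*lambda - nu*exp(lambda)`;
#' this returns the sum over all K*S parameters.
#'
#' @param lambda Matrix (or vector) of log Dirichlet parameters.
#' @param eta,nu Gamma hyperprior shape and rate.
#' @return The summed log density.
#' @export
log_hyperprior <- function(lambda, eta = 0.1, nu = 0.1) {
  if (inherits(lambda, "dmm_model")) lambda <- lambda$lambda
  sum(eta * log(nu) - lgamma(eta) + eta * lambda - nu * exp(lambda))
}

#' EM objective: expected log posterior (Jensen lower bound)
#'
#' `sum_ik z_ik [log pi_k + log p(x_i|alpha_k)]` plus the hyperprior log
#' density. With `z` set to the exact responsibilities of `model` this
#' equals the true log posterior minus the (non-negative) entropy of `z`.
#'
#' @inheritParams responsibilities
#' @param z Responsibility matrix with normalised rows.
#' @param control A [dmm_control()] supplying the hyperprior.
#' @return The objective value.
#' @export
expected_log_posterior <- function(counts, z, model, control = dmm_control()) {
  X <- as_count_matrix(counts)
  le <- log_evidence_matrix(X, model, control$include_coefficient)
  lw <- ifelse(model$weights > 0, log(model$weights), -Inf)
  terms <- z * sweep(le, 2, lw, "+")
  terms[z == 0] <- 0 # 0 * -Inf convention
  sum(terms) + log_hyperprior(model$lambda, control$eta, control$nu)
}

#' Closed-form M-step for the mixture weights
#'
#' With a uniform hyperprior on the weights the maximising update is the
#' column mean of the responsibilities.
#'
#' @param z Responsibility matrix.
#' @return Weight vector of length K summing to one.
#' @export
update_weights <- function(z) {
  w <- colMeans(z)
  w / sum(w)
}

# Responsibility-weighted component objective, gradient and Hessian over
# lambda = log(alpha). Objective is the component's share of the expected
# log posterior (multinomial coefficient omitted: constant in lambda).
component_objective <- function(lam, X, zc, J, eta, nu) {
  a <- exp(lam)
  th <- sum(a)
  Z <- sum(zc)
  dat <- sum(zc * rowSums(lgamma(sweep(X, 2, a, "+")))) - Z * sum(lgamma(a)) -
    sum(zc * lgamma(th + J)) + Z * lgamma(th)
  pri <- sum(eta * lam - nu * a) + length(lam) * (eta * log(nu) - lgamma(eta))
  dat + pri
}

component_gradient <- function(lam, X, zc, J, eta, nu) {
  a <- exp(lam)
  th <- sum(a)
  Z <- sum(zc)
  s1 <- colSums(zc * digamma(sweep(X, 2, a, "+")))
  c0 <- sum(zc * digamma(th + J)) - Z * digamma(th)
  a * (s1 - Z * digamma(a) - c0) + eta - nu * a
}

# Hessian (second derivatives in lambda) of the component objective
component_hessian <- function(lam, X, zc, J, eta, nu) {
  a <- exp(lam)
  th <- sum(a)
  Z <- sum(zc)
  s1 <- colSums(zc * digamma(sweep(X, 2, a, "+")))
  t1 <- colSums(zc * trigamma(sweep(X, 2, a, "+")))
  c0 <- sum(zc * digamma(th + J)) - Z * digamma(th)
  c1 <- sum(zc * trigamma(th + J)) - Z * trigamma(th)
  u <- s1 - Z * digamma(a) - c0
  H <- -c1 * (a %o% a)
  diag(H) <- a * u + a^2 * (t1 - Z * trigamma(a) - c1) - nu * a
  H
}

#' Quasi-Newton M-step for one component
#'
#' Maximises the responsibility-weighted log evidence plus Gamma hyperprior
#' over `lambda = log(alpha)` with BFGS (analytic digamma gradient),
#' followed by damped Newton steps using the analytic Hessian until the
#' gradient sup-norm meets `control$grad_tol`.
#'
#' @inheritParams responsibilities
#' @param z_col Responsibility column for this component (values in
#'   `[0, 1]`).
#' @param lam0 Starting value for `lambda` (length S).
#' @param control A [dmm_control()].
#' @return A list with `lambda`, `value` (objective at the optimum),
#'   `grad_norm` and `converged`.
#' @export
optimize_component <- function(counts, z_col, lam0, control = dmm_control()) {
  X <- as_count_matrix(counts)
  stopifnot(length(z_col) == nrow(X), length(lam0) == ncol(X))
  if (any(z_col < -1e-12) || any(z_col > 1 + 1e-12)) stop("`z_col` entries must be in [0, 1]")
  J <- rowSums(X)
  keep <- z_col > 1e-12
  Xk <- X[keep, , drop = FALSE]
  zk <- z_col[keep]
  Jk <- J[keep]
  eta <- control$eta; nu <- control$nu

  if (sum(zk) < 1e-8) {
    # empty component: hyperprior mode alpha = eta/nu
    lam <- rep(log(eta / nu), length(lam0))
    return(list(lambda = lam,
                value = component_objective(lam, Xk, zk, Jk, eta, nu),
                grad_norm = 0, converged = TRUE, empty = TRUE))
  }

  fn <- function(l) -component_objective(l, Xk, zk, Jk, eta, nu)
  gr <- function(l) -component_gradient(l, Xk, zk, Jk, eta, nu)
  opt <- optim(lam0, fn, gr, method = "BFGS",
               control = list(maxit = control$optim_maxit, reltol = 1e-14))
  lam <- opt$par
  val <- -opt$value

  # Newton polish to drive the gradient below grad_tol; near the optimum the
  # objective moves below double precision, so steps are accepted on a
  # decreasing gradient norm rather than an objective increase
  gnorm <- max(abs(component_gradient(lam, Xk, zk, Jk, eta, nu)))
  for (it in 1:40) {
    if (gnorm <= control$grad_tol) break
    g <- component_gradient(lam, Xk, zk, Jk, eta, nu)
    H <- component_hessian(lam, Xk, zk, Jk, eta, nu)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) step <- g / max(abs(g)) * 0.1
    # ascend: Newton direction for a maximum is -H^{-1} g
    ok <- FALSE
    damp <- 1
    for (h in 1:25) {
      cand <- lam - damp * step
      v <- component_objective(cand, Xk, zk, Jk, eta, nu)
      gn <- max(abs(component_gradient(cand, Xk, zk, Jk, eta, nu)))
      if (is.finite(v) && v >= val - 1e-8 && gn < gnorm) {
        lam <- cand; val <- max(val, v); gnorm <- gn; ok <- TRUE; break
      }
      damp <- damp / 2
    }
    if (!ok) break
  }
  conv <- gnorm <= control$grad_tol
  if (!conv) {
    warning(sprintf("component M-step stopped with gradient sup-norm %.2e > %.0e; best iterate returned",
                    gnorm, control$grad_tol))
  }
  list(lambda = lam, value = val, grad_norm = gnorm, converged = conv, empty = FALSE)
}

# k-means++ seeding then stats::kmeans on relative abundances; returns hard
# assignment vector. Deterministic given the active RNG state.
kmeans_init <- function(P, k) {
  n <- nrow(P)
  if (k == 1) return(rep(1L, n))
  centers <- matrix(NA_real_, k, ncol(P))
  idx <- sample.int(n, 1)
  centers[1, ] <- P[idx, ]
  d2 <- colSums((t(P) - centers[1, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2 / sum(d2))
    centers[j, ] <- P[idx, ]
    d2 <- pmin(d2, colSums((t(P) - centers[j, ])^2))
  }
  if (nrow(unique(centers)) < k) {
    # fewer distinct profiles than components: random hard split
    return(sample(rep_len(seq_len(k), n)))
  }
  km <- suppressWarnings(kmeans(P, centers = centers, iter.max = 50))
  as.integer(km$cluster)
}

#' Fit a Dirichlet multinomial mixture by maximum-posterior EM
#'
#' Alternates the responsibility E-step, the closed-form weight update and a
#' quasi-Newton maximisation of each component's expected log posterior
#' under the Gamma hyperprior, until the relative change of the objective
#' falls below `control$em_tol`. The returned parameters are maximum
#' posterior estimates (MPE). With `restarts > 1` the best final objective
#' wins. Fits are deterministic given `control$seed`.
#'
#' @param counts A count table accepted by [as_count_matrix()].
#' @param k Number of mixture components.
#' @param control A [dmm_control()].
#' @return An object of class `dmm_fit`: `model` (the fitted [dmm_model()]),
#'   `responsibilities` (N x K), `trace` (log posterior per EM cycle,
#'   non-decreasing), `neg_log_posterior`, `converged`, `n_iter`,
#'   `degenerate` (components that emptied), `control` and the validated
#'   count matrix `counts`.
#' @examples
#' sim <- dmm_simulate(dmm_benchmark_spec("k1", seed = 1))
#' fit <- dmm_fit(sim$counts, k = 1)
#' glance(fit)
#' @export
dmm_fit <- function(counts, k, control = dmm_control()) {
  X <- as_count_matrix(counts)
  k <- as.integer(k)
  if (k < 1) stop("`k` must be >= 1")
  if (k > nrow(X)) warning("more components than samples (k > N)")
  best <- NULL
  for (r in seq_len(control$restarts)) {
    fit <- withr::with_seed(control$seed + r - 1L, em_once(X, k, control))
    if (is.null(best) || fit$trace[length(fit$trace)] > best$trace[length(best$trace)]) best <- fit
  }
  best$control <- control
  best$counts <- X
  class(best) <- "dmm_fit"
  best
}

em_once <- function(X, k, control) {
  n <- nrow(X); s <- ncol(X)
  J <- rowSums(X)
  P <- X / ifelse(J > 0, J, 1)

  # initial hard/soft responsibilities
  if (control$init == "kmeans") {
    cl <- kmeans_init(P, k)
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), cl)] <- 1
  } else {
    z <- matrix(rgamma(n * k, shape = 1), n, k)
    z <- z / rowSums(z)
  }

  # initial model from one weight/component update: scale-aware lambda start
  lam <- matrix(NA_real_, k, s)
  for (kk in seq_len(k)) {
    wsum <- sum(z[, kk])
    m0 <- if (wsum > 0) colSums(z[, kk] * P) / wsum else rep(1 / s, s)
    lam[kk, ] <- log(pmax(m0 * (s / 2), 1e-6))
  }
  w <- update_weights(z)
  model <- dmm_model(exp(lam), w)
  colnames(model$alpha) <- colnames(X)

  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  degenerate <- integer(0)
  opt_ok <- TRUE

  for (iter in seq_len(control$max_iter)) {
    # M-step (uses current z; first pass refines the initial model)
    w <- update_weights(z)
    nk <- colSums(z)
    for (kk in seq_len(k)) {
      if (nk[kk] < 1e-8) {
        lam[kk, ] <- rep(log(control$eta / control$nu), s)
        degenerate <- union(degenerate, kk)
        next
      }
      res <- suppressWarnings(
        optimize_component(X, z[, kk], lam[kk, ], control)
      )
      if (!res$converged) opt_ok <- FALSE
      lam[kk, ] <- res$lambda
    }
    model <- dmm_model(exp(lam), w)
    colnames(model$alpha) <- colnames(X)

    # E-step and objective (tight bound = true log posterior)
    es <- e_step(X, model, control$include_coefficient)
    z <- es$z
    lp <- sum(es$log_evidence) +
      log_hyperprior(model$lambda, control$eta, control$nu)
    trace <- c(trace, lp)
    if (is.finite(prev) && abs(lp - prev) <= control$em_tol * abs(lp)) {
      converged <- TRUE
      break
    }
    prev <- lp
  }

  dimnames(z) <- list(rownames(X), paste0("comp", seq_len(k)))
  list(model = model, responsibilities = z, trace = trace,
       neg_log_posterior = -trace[length(trace)], converged = converged,
       n_iter = length(trace), degenerate = degenerate,
       mstep_converged = opt_ok)
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("DMM fit: K = %d, N = %d samples, S = %d taxa\n",
              x$model$k, nrow(x$counts), x$model$s))
  cat(sprintf("negative log posterior: %.4f (%s after %d EM cycles)\n",
              x$neg_log_posterior,
              if (x$converged) "converged" else "iteration cap reached",
              x$n_iter))
  cat("weights:", paste(signif(x$model$weights, 4), collapse = " "), "\n")
  cat("theta:  ", paste(signif(x$model$theta, 4), collapse = " "), "\n")
  if (length(x$degenerate)) cat("degenerate components:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
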