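test_that("responsibilities follow Bayes' rule over components", {
  X <- matrix(c(5, 1, 2, 8), 2, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
  # K = 1: certainty
  expect_equal(unname(responsibilities(X, dmm_model(c(2, 2)))), matrix(1, 2, 1))
  # identical components, equal weights: 1/K everywhere
  m_dup <- dmm_model(rbind(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(unname(responsibilities(X, m_dup)), matrix(1 / 3, 2, 3))
  # hand-computed Bayes ratio for K = 2, unequal priors
  a1 <- c(4, 1); a2 <- c(1, 4)
  m2 <- dmm_model(rbind(a1, a2), weights = c(0.9, 0.1))
  z <- responsibilities(X, m2)
  for (i in 1:2) {
    w <- c(0.9 * exp(log_component_evidence(X[i, ], a1)),
           0.1 * exp(log_component_evidence(X[i, ], a2)))
    expect_equal(unname(z[i, ]), w / sum(w))
  }
  expect_equal(rowSums(z), c(s1 = 1, s2 = 1), tolerance = 1e-12)
})

test_that("Gamma hyperprior density in log space is correct and normalised", {
  # direct evaluation at a single parameter: eta*log(nu) - lgamma(eta)
  # + eta*lambda - nu*exp(lambda) at lambda = 0, eta = nu = 0.1
  expect_equal(log_hyperprior(matrix(0, 1, 1), eta = 0.1, nu = 0.1),
               0.1 * log(0.1) - lgamma(0.1) - 0.1)
  expect_equal(log_hyperprior(matrix(0, 1, 1), eta = 0.1, nu = 0.1),
               -2.582971, tolerance = 1e-6)
  # integrates to 1 over the real line (quadrature oracle)
  q <- integrate(function(l) {
    vapply(l, function(li) exp(log_hyperprior(matrix(li, 1, 1), 1, 1)), numeric(1))
  }, -30, 10, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-7)
  # total scales linearly in the number of parameters
  one <- log_hyperprior(matrix(0.3, 1, 1), 0.5, 0.2)
  expect_equal(log_hyperprior(matrix(0.3, 4, 5), 0.5, 0.2), 20 * one)
})

test_that("expected log posterior is the Jensen bound of the true log posterior", {
  X <- toy_two_component_counts(seed = 9, n_per = 5)
  ctl <- dmm_control(seed = 1)
  m <- dmm_model(rbind(rep(1, ncol(X)), rep(2, ncol(X))), weights = c(0.5, 0.5))
  es <- dmmix:::e_step(X, m)
  lp_true <- sum(es$log_evidence) + log_hyperprior(m$lambda, ctl$eta, ctl$nu)
  bound <- expected_log_posterior(X, es$z, m, ctl)
  entropy <- -sum(ifelse(es$z > 0, es$z * log(es$z), 0))
  # tight-bound identity: true log posterior = bound + responsibility entropy
  expect_equal(lp_true, bound + entropy, tolerance = 1e-8)
  expect_gte(lp_true, bound)
  # E-step responsibilities maximise the bound at fixed parameters
  set.seed(5)
  for (rep in 1:5) {
    z_other <- matrix(rgamma(nrow(X) * 2, 1), nrow(X), 2)
    z_other <- z_other / rowSums(z_other)
    expect_gte(bound, expected_log_posterior(X, z_other, m, ctl))
  }
  # K = 1 with the hyperprior removed is the dataset log evidence
  m1 <- dmm_model(rep(1.5, ncol(X)))
  z1 <- matrix(1, nrow(X), 1)
  expect_equal(
    expected_log_posterior(X, z1, m1, ctl) - log_hyperprior(m1$lambda, ctl$eta, ctl$nu),
    sum(dmmix:::e_step(X, m1)$log_evidence)
  )
})

test_that("weight update is the responsibility column mean", {
  expect_equal(update_weights(matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE)),
               c(1, 0))
  expect_equal(update_weights(matrix(1 / 3, 5, 3)), rep(1 / 3, 3))
  expect_equal(update_weights(matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)),
               c(0.75, 0.25))
})

test_that("component M-step reaches a stationary point with the analytic gradient", {
  set.seed(11)
  X <- matrix(rpois(15, 10), 5, 3, dimnames = list(paste0("s", 1:5), paste0("t", 1:3)))
  ctl <- dmm_control()
  z_col <- runif(5, 0.2, 1)
  res <- optimize_component(X, z_col, rep(0, 3), ctl)
  expect_lte(res$grad_norm, 1e-5)
  # finite-difference gradient oracle at the optimum
  f <- function(l) dmmix:::component_objective(l, X, z_col, rowSums(X), ctl$eta, ctl$nu)
  expect_lt(max(abs(fd_gradient(f, res$lambda))), 1e-3)
  # symmetry: taxon-exchangeable data and start give symmetric lambda
  Xs <- matrix(c(4, 4, 2, 2, 7, 7), 3, 2, byrow = TRUE,
               dimnames = list(paste0("s", 1:3), c("t1", "t2")))
  rs <- optimize_component(Xs, rep(1, 3), c(0, 0), ctl)
  expect_equal(rs$lambda[1], rs$lambda[2], tolerance = 1e-8)
})

test_that("single-component MPE recovers a known Dirichlet-multinomial mean", {
  sim <- dmm_simulate(dmm_sim_spec(400, c(0.5, 0.3, 0.15, 0.05), theta = 20,
                                   library_size = list(law = "fixed", j = 500), seed = 21))
  X <- as_count_matrix(sim$counts)
  ctl <- dmm_control()
  res <- optimize_component(X, rep(1, nrow(X)), rep(log(0.5), 4), ctl)
  m_hat <- exp(res$lambda) / sum(exp(res$lambda))
  expect_lt(sum(abs(m_hat - c(0.5, 0.3, 0.15, 0.05))), 0.02)
})

test_that("EM fit is monotone, seeded-deterministic and recovers simulated parameters", {
  sim1 <- dmm_simulate(dmm_benchmark_spec("k1", seed = 42))
  fit1 <- dmm_fit(sim1$counts, 1)
  expect_true(all(diff(fit1$trace) >= -1e-8))
  rec1 <- recovery_report(sim1, fit1)
  expect_lte(rec1$per_component$mean_l1, 0.03)
  expect_lte(rec1$per_component$theta_rel_err, 0.25)

  sim2 <- dmm_simulate(dmm_benchmark_spec("k2", seed = 1))
  fit2 <- dmm_fit(sim2$counts, 2)
  expect_true(all(diff(fit2$trace) >= -1e-8))
  rec2 <- recovery_report(sim2, fit2)
  expect_gte(rec2$accuracy, 0.95)

  # identical config and seed reproduce the fit exactly
  fit2b <- dmm_fit(sim2$counts, 2)
  expect_identical(length(fit2$trace), length(fit2b$trace))
  expect_equal(fit2$neg_log_posterior, fit2b$neg_log_posterior, tolerance = 1e-12)
  expect_equal(fit2$model$alpha, fit2b$model$alpha)
})

test_that("label-permutation of a fit leaves the objective unchanged", {
  sim2 <- dmm_simulate(dmm_benchmark_spec("k2", seed = 2))
  X <- as_count_matrix(sim2$counts)
  fit <- dmm_fit(X, 2)
  perm <- c(2, 1)
  m_perm <- dmm_model(fit$model$alpha[perm, ], fit$model$weights[perm])
  ctl <- fit$control
  lp <- function(m) {
    es <- dmmix:::e_step(X, m, ctl$include_coefficient)
    sum(es$log_evidence) + log_hyperprior(m$lambda, ctl$eta, ctl$nu)
  }
  expect_equal(lp(fit$model), lp(m_perm), tolerance = 1e-8)
})

test_that("all-zero taxon columns stay finite under the Gamma hyperprior", {
  sim <- dmm_simulate(dmm_benchmark_spec("k1", seed = 8))
  X <- as_count_matrix(sim$counts)
  X <- cbind(X, neverseen = 0)
  fit <- dmm_fit(X, 1)
  expect_true(all(is.finite(fit$model$alpha)))
  expect_true(all(fit$model$alpha > 0))
  # the unobserved taxon is pulled toward the prior scale, far below the data
  expect_lt(fit$model$alpha[1, "neverseen"], min(fit$model$alpha[1, 1:10]))
})

test_that("more components than samples triggers a warning, not an error", {
  X <- matrix(c(5, 1, 2, 8), 2, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_warning(fit <- dmm_fit(X, 3, dmm_control(max_iter = 10)), "k > N")
  expect_s3_class(fit, "dmm_fit")
})
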