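# Independent numerical oracles used across the suite. These deliberately
# avoid the package's analytic code paths.

# all count vectors of length s summing to j (exhaustive enumeration)
enumerate_counts <- function(s, j) {
  if (s == 1) return(matrix(j, 1, 1))
  out <- list()
  for (x1 in 0:j) {
    rest <- enumerate_counts(s - 1, j - x1)
    out[[length(out) + 1]] <- cbind(x1, rest)
  }
  unname(do.call(rbind, out))
}

# Dirichlet draws via normalised Gammas
rdirichlet_oracle <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), n)
  g / rowSums(g)
}

# central finite-difference gradient
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# central finite-difference Hessian
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- rep(0, p); ei[i] <- h
    ej <- rep(0, p); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
  }
  H
}

# small well-separated two-component count matrix for Hessian/Laplace checks
toy_two_component_counts <- function(seed = 42, n_per = 8) {
  spec2 <- dmm_benchmark_spec("k2", seed = seed)
  mA <- spec2$means[1, 1:8] / sum(spec2$means[1, 1:8])
  mB <- spec2$means[2, 6:13] / sum(spec2$means[2, 6:13])
  sA <- dmm_simulate(dmm_sim_spec(n_per, mA, theta = 40,
                                  library_size = list(law = "fixed", j = 200), seed = seed))
  sB <- dmm_simulate(dmm_sim_spec(n_per, mB, theta = 40,
                                  library_size = list(law = "fixed", j = 200), seed = seed + 1L))
  XA <- as_count_matrix(sA$counts)
  XB <- as_count_matrix(sB$counts)
  rownames(XA) <- paste0("A", seq_len(n_per))
  rownames(XB) <- paste0("B", seq_len(n_per))
  rbind(XA, XB)
}
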