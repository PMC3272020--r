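---
title: "Dirichlet multinomial mixtures: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet multinomial mixtures: model, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmmix)
```

## The model

A taxa-by-sample count matrix `X` (N samples, S taxa) is modelled in three
stages. Each sample `i` carries a latent community composition `p_i` on the
S-simplex; its observed counts are a multinomial draw of the library size
`J_i` from `p_i` (sampling reads with replacement from the community). The
compositions themselves are drawn from a mixture of K Dirichlet components:
component k has parameters `alpha_k`, which factor into a precision
`theta_k = sum(alpha_k)` and a mean composition `m_k = alpha_k / theta_k`.
A large `theta` concentrates communities tightly around `m`; a small
`theta` spreads them out. We read each component as a *metacommunity* — a
pool with a typical composition and a characteristic variability — and the
mixture weights `pi_k` as the frequencies with which samples derive from
each pool.

Because the Dirichlet is conjugate to the multinomial, the latent `p_i`
integrates out in closed form. The per-sample marginal evidence under one
component is

```
p(x | alpha) = C(x) * B(alpha + x) / B(alpha),   B(a) = prod(Gamma(a_j)) / Gamma(sum(a)),
```

with `C(x)` the multinomial coefficient, and the mixture evidence is the
`pi`-weighted sum. This closed form is what makes the whole pipeline
tractable: fitting, model selection and classification all reduce to sums
of log-Gamma terms.

Two conventions are worth stating explicitly because they change reported
numbers, not inferences:

* **Multinomial coefficient.** `C(x)` is constant in the parameters, so it
  affects no fit, comparison or responsibility. We include it by default so
  evidences are true probabilities over count vectors — the
  exhaustive-enumeration normalisation test then checks `sum = 1` exactly
  rather than up to a data-dependent constant. The convention is recorded
  in every model file, and comparisons must hold it fixed.
* **All arithmetic is in log space.** Library sizes of 10^4 make
  Gamma-function values overflow immediately; nothing in the package
  exponentiates a Gamma value directly, and mixture sums use log-sum-exp.

## Hyperprior

Each `alpha_kj` carries an independent Gamma(eta, nu) hyperprior. On the
unconstrained scale `lambda = log(alpha)` used for optimisation its log
density is `eta*log(nu) - lgamma(eta) + eta*lambda - nu*exp(lambda)`. The
defaults `eta = nu = 0.1` (prior mean 1, variance 10) are deliberately
vague: their practical role is numerical, keeping parameters of rare and
unobserved taxa finite and positive instead of drifting to `-Inf` on the
log scale. Both values are exposed in `dmm_control()` and recorded in
output. With data present the likelihood dominates; we observed fitted
means to be insensitive to `eta, nu` over an order of magnitude either way.

## Fitting: maximum-posterior EM

`dmm_fit()` maximises the log posterior (evidence times hyperprior) over
`Theta = {pi_k, lambda_k}` with EM on the component-indicator latent
variables:

1. **E-step** — responsibilities `z_ik` by Bayes' rule from the current
   component evidences (log-sum-exp stabilised).
2. **Weight M-step** — closed form `pi_k = mean_i(z_ik)` (uniform
   hyperprior on the weights).
3. **Component M-step** — each `lambda_k` maximises its
   responsibility-weighted log evidence plus hyperprior terms by BFGS with
   the analytic digamma gradient, followed by damped Newton steps using the
   analytic Hessian until the gradient sup-norm is below `grad_tol`
   (default 1e-5). Near the optimum the objective moves below double
   precision, so the polish accepts steps on a decreasing gradient norm.

Iteration stops when the relative change of the objective falls below
`em_tol` (default 1e-6) or after `max_iter = 250` cycles. The recorded
trace evaluates the bound at the tight point (just after an E-step), where
it equals the true log posterior, so it is non-decreasing up to 1e-8
numerical slack — asserted by the tests on every fit.

**Initialisation and restarts.** The default initialisation runs k-means
(with k-means++ seeding from the run seed) on row-normalised relative
abundances to get hard initial assignments; `random_soft` draws
responsibility rows from a symmetric Dirichlet instead. Initial
`lambda_k` is the log of the responsibility-weighted mean relative
abundance times an initial precision guess of `S/2`, floored at
`log(1e-6)` so absent taxa start finite. EM on mixtures has local optima:
on the three-component benchmark below, a single k-means start
occasionally merges two true clusters and settles ~10^3 log-units below
the global mode, which then misleads model selection upward. The default
is therefore `restarts = 3` independent seeded starts, keeping the best
final objective; fits remain deterministic given `seed`. Ties in k-means
assignment and responsibility argmax break toward the lowest index.

**Degenerate components.** A component whose responsibility mass falls
below 1e-8 is reset to the hyperprior mode `alpha = eta/nu` and flagged;
`select_k` sweeps therefore always complete.

## Model selection: Laplace evidence

The posterior mode alone cannot choose K — more components always fit
better. `laplace_evidence()` approximates the log model evidence by a
Gaussian expansion at the maximum posterior estimate:
`log p(X|K) ≈ log p(X, Theta*) + (P/2) log 2pi - (1/2) log det H`. The
negative is reported so smaller is better, and `select_k()` takes the
argmin over a K range. AIC/BIC-style heuristics are deliberately not used
for selection.

`H` is the analytic Hessian of the negative log posterior with the
responsibilities frozen at their converged values — the surface the EM
actually maximised. It is block diagonal: per-component S×S blocks of
digamma/trigamma terms plus the `nu*exp(lambda)` hyperprior diagonal, and
by default a (K−1)-dimensional block for softmax-reparameterised weights,
giving `P = K*S + K - 1`. Whether the weight block belongs in `P` is a
judgement call (the mode of the weights is determined by the same data);
both conventions are implemented (`weight_block` flag) and the choice is
recorded in output. Near-singular Hessians are handled by flooring
eigenvalues at 1e-10 and flagging the result rather than failing.
Correctness is checked two ways: the full Hessian against central finite
differences (1e-4 norm-relative), and the Laplace log evidence against
adaptive 2-D quadrature of the actual evidence integrand on a K=1, S=2
problem (within 2%).

Credible intervals for component compositions use the diagonal of the
inverse Hessian as the variance of `lambda_kj`; endpoints are
`exp(lambda ± 2*sigma)` mapped to relative abundance against the other
parameters held fixed, in percent. Transforming endpoints from the
`lambda` scale (rather than computing on the abundance scale directly)
keeps them inside (0, 100) by construction.

## Metacommunity summaries

Samples are hard-assigned to the component with maximal responsibility.
Component compositions are compared to a reference — conventionally the
single-component fit to the same data — through
`d_k = 100 * sum_j |m_kj - m_ref_j|`, which ranges from 0% (identical) to
200% (disjoint support). The per-taxon contributions are ranked with a
cumulative column so the taxa carrying the difference head the table.
"Posterior mean" of a component here means `m_k = alpha_k/theta_k` at the
MPE; a class-level mean is the weight-averaged `sum_k pi_k m_k`.
Components of two fits are matched by Bray–Curtis distance between mean
vectors; the matching is greedy nearest-first one-to-one (the full
distance matrix is always attached for audit) rather than an optimal
assignment, which matches how such correspondences are read in practice.

## Generative classification

`fit_classifier()` fits one mixture per class (each with its own
evidence-selected K up to `k_max`) and sets class priors to observed
frequencies. A new sample's class posterior marginalises its latent
composition: `P(c|x) ∝ P(c) * sum_k pi_k^(c) p(x|alpha_k^(c))`, in log
space. Any number of classes works; binary outputs (ROC) take a designated
positive class.

Leave-one-out validation refits the per-class mixtures with each sample
held out. By default the per-class K is re-selected inside every fold —
the faithful protocol, since K is part of the estimator — with a fast mode
(`reselect_k = FALSE`) that reuses the full-data K, labelled in the
output. Thresholded classification uses the `>=` rule, and the ROC curve
lowers a threshold from 1 to 0 at the distinct sample probabilities,
prepending the (0, 0) point where needed; AUC is the trapezoid area.
Whether splitting by class is supported at all is tested by comparing the
sum of per-class negative Laplace evidences with the pooled fit's
(`compare_class_fit()`).

## The simulator and what passing tests mean

`dmm_simulate()` draws from the exact generative chain — component from
`pi`, composition from `Dirichlet(theta_k * m_k)`, library size from a
configurable law, counts from the multinomial. Library sizes default to a
log-normal with median 1,600 (sdlog 0.75) truncated to [50, 11000],
emulating the two-orders-of-magnitude spread of per-sample read counts in
real amplicon surveys. Sparsity emerges from small `theta` and skewed `m`
rather than from explicit zero-inflation, which keeps the generator inside
the model class the tool fits.

Three fixed benchmark conditions (`dmm_benchmark_spec()`) are used across
tests and the acceptance script:

* `k1`: K=1, S=10, N=100, theta=50, geometrically skewed mean;
* `k2`: K=2, S=20, N=200, theta=(50, 50), disjoint 5-taxon dominant blocks
  holding 80% of the mass, shared tail;
* `k3`: K=3, S=12, N=150, theta=100, disjoint 4-taxon blocks holding 85%.

These sizes keep the full suite and the acceptance sweep to a few minutes
while leaving the statistical questions non-trivial. On them, the fitted
mean recovers the truth to ~0.03 L1 (K=1; the expected error at N=100 is
~0.028 with seed-to-seed sd ~0.009, so single draws straddle 0.03),
`theta` to a few percent, hard assignments are ≥95% correct on the
separated K=2 condition, and K selection over 20 seeded replicates picks
the generating K in ≥18.

What passing does **not** show: real communities are not
Dirichlet-multinomial. Taxon correlations beyond the (negative)
compositional ones, sequencing error, chimeras and taxonomic
misclassification are absent from the generator, and real cluster
structure is far less separated than the benchmarks. Results on real data
should be read through the model-checking lens the evidence provides, not
as ground truth.

## Numerical choices, degenerate inputs, limitations

* Samples with `J_i = 0` are valid (evidence 1) but flagged at load time.
* All-zero taxon columns stay finite and positive via the hyperprior.
* `K > N` is allowed with a warning; emptied components are flagged.
* Evidence values are invariant to taxon-column permutation (tested to
  1e-8); label permutations of components permute, never change, a fit.
* The Laplace approximation assumes a locally Gaussian posterior; for
  tiny N or near-degenerate components the Hessian flag
  (`hessian_condition_ok`) should be checked before trusting the evidence
  differences.
* The dense per-component Hessian is S×S; for OTU tables with thousands of
  columns the Laplace step becomes the bottleneck and K selection should
  be run on an aggregated (e.g. genus-level) table.
* Responsibilities are frozen when forming the Hessian; the curvature of
  the E-step mapping is not propagated. This matches the optimised
  surface but slightly understates parameter uncertainty.
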