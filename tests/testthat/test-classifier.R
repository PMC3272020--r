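test_that("class priors are observed frequencies and tiny classes are rejected", {
  sim <- simulate_two_classes(n_per_class = 10, seed = 2)
  X <- as_count_matrix(sim$counts)
  y <- sim$labels
  y[1:5] <- "classB" # unbalance: 5 A, 35... no: 20 samples, now 5 A / 15 B
  clf <- fit_classifier(X, y, k_max = 1)
  expect_equal(unname(clf$priors), unname(table(y)[clf$classes] / length(y)),
               ignore_attr = TRUE)
  expect_equal(sum(clf$priors), 1)
  y_bad <- y; y_bad[] <- "classB"; y_bad[1] <- "classA"
  expect_error(fit_classifier(X, y_bad, k_max = 1), "at least 2 samples")
  expect_error(fit_classifier(X, rep("one", nrow(X)), k_max = 1), "at least 2 classes")
})

test_that("identical class models give posteriors equal to the priors", {
  sim <- simulate_two_classes(n_per_class = 8, seed = 5)
  X <- as_count_matrix(sim$counts)
  clf <- fit_classifier(X, sim$labels, k_max = 1)
  # force both classes to share one model; only the priors differ
  clf$fits$classB <- clf$fits$classA
  clf$priors <- c(classA = 0.3, classB = 0.7)
  pred <- predict(clf, X)
  expect_equal(pred$classA, rep(0.3, nrow(X)), tolerance = 1e-12)
  expect_equal(pred$classB, rep(0.7, nrow(X)), tolerance = 1e-12)
  # posteriors always sum to one
  expect_equal(pred$classA + pred$classB, rep(1, nrow(X)), tolerance = 1e-12)
})

test_that("posterior is scale-coherent in the priors", {
  sim <- simulate_two_classes(n_per_class = 8, seed = 6)
  X <- as_count_matrix(sim$counts)
  clf <- fit_classifier(X, sim$labels, k_max = 1)
  p1 <- predict(clf, X)
  clf2 <- clf
  clf2$priors <- clf$priors * 4 # unnormalised priors: posteriors unchanged
  p2 <- predict(clf2, X)
  expect_equal(p1$classA, p2$classA, tolerance = 1e-12)
})

test_that("a diagnostic taxon drives the class posterior to certainty", {
  # class A concentrated on taxon 1, class B on taxon 2
  fitA <- list(model = dmm_model(c(50, 1, 1)))
  fitB <- list(model = dmm_model(c(1, 50, 1)))
  clf <- structure(
    list(classes = c("A", "B"), priors = c(A = 0.5, B = 0.5),
         fits = list(A = fitA, B = fitB), k = c(A = 1L, B = 1L),
         taxa = paste0("t", 1:3), control = dmm_control()),
    class = "dmm_classifier")
  x <- matrix(c(30, 0, 0), 1, dimnames = list("s1", paste0("t", 1:3)))
  pred <- predict(clf, x)
  expect_gt(pred$A, 0.99)
})

test_that("leave-one-out validation is per-sample, deterministic and accurate when separable", {
  sim <- simulate_two_classes(n_per_class = 15, seed = 7)
  loo <- loo_validate(sim$counts, sim$labels, k_max = 1)
  expect_equal(nrow(loo), 30)
  expect_setequal(loo$sample_id, names(sim$labels))
  err <- mean(loo$.pred_class != loo$actual)
  expect_lte(err, 0.05)
  loo2 <- loo_validate(sim$counts, sim$labels, k_max = 1)
  expect_equal(loo$classB, loo2$classB, tolerance = 1e-15)
  # fast mode reusing the full-data K is labelled
  loo3 <- loo_validate(sim$counts, sim$labels, k_max = 1, reselect_k = FALSE)
  expect_false(attr(loo3, "reselect_k"))
})

test_that("confusion matrices reproduce printed error rates at threshold 0.5", {
  # reconstruct per-sample predictions from tabulated confusion counts
  expand_conf <- function(m) {
    # rows = actual (neg, pos); cols = predicted (neg, pos)
    actual <- rep(c("Lean", "Obese"), times = rowSums(m))
    probs <- c(rep(0.1, m[1, 1]), rep(0.9, m[1, 2]),
               rep(0.1, m[2, 1]), rep(0.9, m[2, 2]))
    list(probs = probs, actual = actual)
  }
  dm <- expand_conf(rbind(c(33, 28), c(29, 164)))
  cm <- confusion_and_error(dm$probs, dm$actual, threshold = 0.5, positive = "Obese")
  expect_equal(unname(cm$table), rbind(c(33, 28), c(29, 164)))
  expect_equal(cm$error_rate, 57 / 254)
  expect_equal(round(100 * cm$error_rate, 1), 22.4)
  rf <- expand_conf(rbind(c(19, 42), c(5, 188)))
  cm_rf <- confusion_and_error(rf$probs, rf$actual, threshold = 0.5, positive = "Obese")
  expect_equal(cm_rf$error_rate, 47 / 254)
  expect_equal(round(100 * cm_rf$error_rate, 1), 18.5)
  # perfect predictions give a diagonal matrix and zero error
  cm0 <- confusion_and_error(c(0.9, 0.9, 0.1), c("Obese", "Obese", "Lean"),
                             positive = "Obese")
  expect_equal(cm0$error_rate, 0)
  expect_equal(sum(cm0$table) - sum(diag(cm0$table)), 0)
  # the threshold rule is >= : probability exactly at threshold goes positive
  cm_eq <- confusion_and_error(c(0.5, 0.2), c("Obese", "Lean"),
                               threshold = 0.5, positive = "Obese")
  expect_equal(unname(cm_eq$table["Obese", "Obese"]), 1)
  expect_equal(cm_eq$error_rate, 0)
})

test_that("ROC construction and AUC follow the threshold-lowering rule", {
  roc <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c("pos", "neg", "pos", "neg"), positive = "pos")
  expect_equal(roc$auc, 0.75)
  # endpoints
  expect_equal(roc$points$fpr_pct[1], 0)
  expect_equal(roc$points$tpr_pct[1], 0)
  expect_equal(roc$points$fpr_pct[nrow(roc$points)], 100)
  expect_equal(roc$points$tpr_pct[nrow(roc$points)], 100)
  expect_true(all(diff(roc$points$fpr_pct) >= 0))
  expect_true(all(diff(roc$points$tpr_pct) >= 0))
  # perfect and anti-ordered scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), positive = "p")$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c("p", "p", "n", "n"), positive = "p")$auc, 0)
  # invariance under strictly monotone score transforms
  set.seed(8)
  s <- runif(30)
  y <- ifelse(runif(30) < plogis(5 * (s - 0.5)), "p", "n")
  if (length(unique(y)) == 2) {
    a1 <- roc_auc(s, y, positive = "p")$auc
    a2 <- roc_auc(plogis(3 * s + 1), y, positive = "p")$auc
    expect_equal(a1, a2)
  }
  expect_error(roc_auc(c(0.1, 0.2), c("p", "p")), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  s <- runif(40)
  y <- ifelse(runif(40) < plogis(4 * (s - 0.4)), "p", "n")
  a_ours <- roc_auc(s, y, positive = "p")$auc
  a_ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          levels = c("n", "p"), direction = "<",
                                          quiet = TRUE)))
  expect_equal(a_ours, a_ref, tolerance = 1e-12)
})

test_that("class-split evidence comparison favours real structure only", {
  # classes drawn from different metacommunities: split wins
  sim <- simulate_two_classes(n_per_class = 12, seed = 9)
  cmp <- compare_class_fit(sim$counts, sim$labels, k_max = 1)
  expect_true(cmp$split_favoured)
  expect_lt(cmp$difference, 0)
  # random labels on homogeneous data: split not favoured in most runs
  wins <- 0
  for (seed in 1:20) {
    sim1 <- dmm_simulate(dmm_sim_spec(30, c(0.4, 0.3, 0.2, 0.06, 0.04), theta = 50,
                                      library_size = list(law = "fixed", j = 400),
                                      seed = 100 + seed))
    X <- as_count_matrix(sim1$counts)
    y <- withr::with_seed(seed, sample(rep(c("g1", "g2"), each = 15)))
    names(y) <- rownames(X)
    cmp1 <- compare_class_fit(X, y, k_max = 1)
    if (cmp1$difference >= 0) wins <- wins + 1
  }
  expect_gte(wins, 18)
  expect_error(compare_class_fit(X, setNames(rep("g1", 30), rownames(X))), "2 classes")
})
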