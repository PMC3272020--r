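#' Fit a generative DMM classifier
#'
#' Associates a separate Dirichlet multinomial mixture with each class:
#' per-class K is chosen by Laplace evidence over `1:k_max`, and class
#' priors are the observed class frequencies. Prediction applies Bayes'
#' rule with the class mixture evidences (the latent community vector of
#' the sample to classify is marginalised out analytically).
#'
#' @param counts A count table accepted by [as_count_matrix()].
#' @param labels Class labels: a vector aligned with the samples, a named
#'   vector (sample ID -> class), or a two-column data frame.
#' @param k_max Largest per-class component count considered.
#' @param control A [dmm_control()].
#' @return An object of class `dmm_classifier`: `classes`, `priors`,
#'   `selects` (per-class [select_k()] results), `fits` (best per-class
#'   fit), `k` (selected per-class K) and `taxa`.
#' @examples
#' \donttest{
#' sim <- simulate_two_classes(n_per_class = 20, seed = 1)
#' clf <- fit_classifier(sim$counts, sim$labels, k_max = 1)
#' clf$priors
#' }
#' @export
fit_classifier <- function(counts, labels, k_max = 3, control = dmm_control()) {
  X <- as_count_matrix(counts)
  y <- align_labels(labels, rownames(X))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  sizes <- table(y)
  if (any(sizes < 2)) {
    stop("every class needs at least 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  selects <- lapply(classes, function(cl) {
    select_k(X[y == cl, , drop = FALSE], k_range = seq_len(k_max), control = control)
  })
  names(selects) <- classes
  structure(
    list(classes = classes,
         priors = setNames(as.numeric(sizes[classes] / length(y)), classes),
         selects = selects,
         fits = lapply(selects, function(s) s$best_fit),
         k = vapply(selects, function(s) s$best_k, integer(1)),
         taxa = colnames(X),
         k_max = k_max,
         control = control),
    class = "dmm_classifier"
  )
}

align_labels <- function(labels, ids) {
  if (is.data.frame(labels)) labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) stop("labels missing for samples: ", paste(missing, collapse = ", "))
    return(as.character(labels[ids]))
  }
  if (length(labels) != length(ids)) stop("labels must align with samples")
  as.character(labels)
}

#' @export
print.dmm_classifier <- function(x, ...) {
  cat("Generative DMM classifier\n")
  for (cl in x$classes) {
    cat(sprintf("  class %-10s prior %.3f, K = %d\n", cl, x$priors[[cl]], x$k[[cl]]))
  }
  invisible(x)
}

#' Posterior class probabilities for new samples
#'
#' `P(class c | x) proportional to P(c) * sum_k pi_k^(c) p(x | alpha_k^(c))`,
#' computed in log space and normalised across classes.
#'
#' @param object A [fit_classifier()] model.
#' @param newdata A count table over the same taxa.
#' @param ... Unused.
#' @return A tibble with `sample_id`, one probability column per class, and
#'   `.pred_class` (argmax).
#' @export
predict.dmm_classifier <- function(object, newdata, ...) {
  X <- as_count_matrix(newdata)
  if (ncol(X) != length(object$taxa)) {
    stop(sprintf("newdata has %d taxa but the classifier was trained on %d",
                 ncol(X), length(object$taxa)))
  }
  lp <- vapply(object$classes, function(cl) {
    model <- object$fits[[cl]]$model
    es <- e_step(X, model, object$control$include_coefficient)
    log(object$priors[[cl]]) + es$log_evidence
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X), dimnames = list(rownames(X), object$classes))
  post <- t(apply(lp, 1, function(r) exp(r - logsumexp(r))))
  out <- tibble::as_tibble(post)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(X)), out)
  out$.pred_class <- object$classes[max.col(post, ties.method = "first")]
  out
}

#' Leave-one-out validation of the generative classifier
#'
#' Removes each sample in turn, retrains the per-class mixtures on the
#' remaining samples, and predicts the held-out sample. By default the
#' per-class component count is re-selected within every fold
#' (`reselect_k = TRUE`, the faithful but expensive mode); with
#' `reselect_k = FALSE` the per-class K chosen on the full data is reused.
#' Deterministic given `control$seed`.
#'
#' @inheritParams fit_classifier
#' @param reselect_k Re-run per-class K selection in every fold.
#' @return A tibble with `sample_id`, `actual`, one probability column per
#'   class and `.pred_class`; the validation mode is recorded in
#'   `attr(, "reselect_k")`. Folds that would empty a class are skipped
#'   with a warning.
#' @export
loo_validate <- function(counts, labels, k_max = 3, control = dmm_control(),
                         reselect_k = TRUE) {
  X <- as_count_matrix(counts)
  y <- align_labels(labels, rownames(X))
  classes <- sort(unique(y))
  fixed_k <- NULL
  if (!reselect_k) fixed_k <- fit_classifier(X, y, k_max = k_max, control = control)$k
  rows <- list()
  for (i in seq_len(nrow(X))) {
    ytr <- y[-i]
    if (any(table(factor(ytr, levels = classes)) < 2)) {
      warning("fold for sample ", rownames(X)[i], " would leave a class with < 2 samples; skipped")
      next
    }
    Xtr <- X[-i, , drop = FALSE]
    fits <- lapply(classes, function(cl) {
      Xc <- Xtr[ytr == cl, , drop = FALSE]
      if (reselect_k) select_k(Xc, seq_len(k_max), control)$best_fit
      else dmm_fit(Xc, fixed_k[[cl]], control)
    })
    names(fits) <- classes
    priors <- table(factor(ytr, levels = classes)) / length(ytr)
    lp <- vapply(classes, function(cl) {
      log(priors[[cl]]) +
        e_step(X[i, , drop = FALSE], fits[[cl]]$model, control$include_coefficient)$log_evidence
    }, numeric(1))
    post <- exp(lp - logsumexp(lp))
    row <- tibble::as_tibble(as.list(setNames(post, classes)))
    row <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(X)[i], actual = y[i]), row)
    row$.pred_class <- classes[which.max(post)]
    rows[[length(rows) + 1]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reselect_k") <- reselect_k
  out
}

#' Confusion matrix and error rate at a probability threshold
#'
#' Predicts the positive class when its probability is greater than or
#' equal to `threshold` and tabulates actual against predicted classes.
#'
#' @param probs Per-sample probabilities of the positive class.
#' @param labels Actual class labels (binary).
#' @param threshold Classification threshold in `[0, 1]` (default 0.5; the
#'   comparison is `>=`).
#' @param positive The positive class; defaults to the last sorted level.
#' @return An object of class `dmm_confusion`: `table` (rows = actual,
#'   columns = predicted), `error_rate` (misclassified fraction), `n` and
#'   `threshold`.
#' @examples
#' cm <- confusion_and_error(c(0.9, 0.2, 0.7), c("B", "A", "A"), positive = "B")
#' cm$error_rate
#' @export
confusion_and_error <- function(probs, labels, threshold = 0.5, positive = NULL) {
  if (length(probs) != length(labels)) stop("`probs` and `labels` differ in length")
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("binary confusion requires exactly 2 classes present")
  if (is.null(positive)) positive <- classes[2]
  negative <- setdiff(classes, positive)
  pred <- ifelse(probs >= threshold, positive, negative)
  tab <- table(actual = factor(labels, levels = c(negative, positive)),
               predicted = factor(pred, levels = c(negative, positive)))
  structure(
    list(table = unclass(tab),
         error_rate = (sum(tab) - sum(diag(tab))) / sum(tab),
         n = sum(tab),
         threshold = threshold,
         positive = positive),
    class = "dmm_confusion"
  )
}

#' @export
print.dmm_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (threshold %.2f, positive = %s), error rate %.1f%%\n",
              x$threshold, x$positive, 100 * x$error_rate))
  print(x$table)
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Lowers a threshold from 1.0 to 0.0 with intervals defined by the sample
#' probabilities; at each threshold, samples with score `>=` threshold are
#' called positive and the false-positive and true-positive percentages are
#' recorded. The area under the curve is computed by the trapezoid rule.
#'
#' @param scores Per-sample scores for the positive class (higher = more
#'   likely positive).
#' @param labels Actual class labels (binary; both classes must occur).
#' @param positive The positive class; defaults to the last sorted level.
#' @return An object of class `dmm_roc`: a tibble `points` with columns
#'   `threshold`, `fpr_pct`, `tpr_pct`, plus `auc` in `[0, 1]`.
#' @examples
#' roc <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c("pos", "neg", "pos", "neg"), positive = "pos")
#' roc$auc # 0.75
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("`scores` and `labels` differ in length")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("ROC requires both classes present")
  if (is.null(positive)) positive <- classes[2]
  is_pos <- labels == positive
  thr <- unique(c(1, sort(unique(scores), decreasing = TRUE), 0))
  thr <- sort(thr, decreasing = TRUE)
  tpr <- vapply(thr, function(t) 100 * mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) 100 * mean(scores[!is_pos] >= t), numeric(1))
  if (fpr[1] > 0 || tpr[1] > 0) { # ensure the curve starts at (0, 0)
    thr <- c(Inf, thr); fpr <- c(0, fpr); tpr <- c(0, tpr)
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2) / 1e4
  structure(
    list(points = tibble::tibble(threshold = thr, fpr_pct = fpr, tpr_pct = tpr),
         auc = auc, positive = positive),
    class = "dmm_roc"
  )
}

#' @export
print.dmm_roc <- function(x, ...) {
  cat(sprintf("ROC curve (%d thresholds), AUC = %.3f (positive = %s)\n",
              nrow(x$points), x$auc, x$positive))
  invisible(x)
}

#' Compare per-class fits with a pooled fit
#'
#' Tests whether splitting the data by class is supported by the evidence:
#' the sum of the per-class negative Laplace evidences is compared with the
#' negative Laplace evidence of a pooled fit that ignores the class labels.
#' A lower (smaller) split sum favours the class structure.
#'
#' @inheritParams fit_classifier
#' @return A tibble with one row: `split_neg_evidence`,
#'   `pooled_neg_evidence`, `difference` (split minus pooled) and
#'   `split_favoured`.
#' @export
compare_class_fit <- function(counts, labels, k_max = 3, control = dmm_control()) {
  X <- as_count_matrix(counts)
  y <- align_labels(labels, rownames(X))
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  clf <- fit_classifier(X, y, k_max = k_max, control = control)
  split_ne <- sum(vapply(clf$selects, function(s) min(s$table$neg_evidence, na.rm = TRUE), numeric(1)))
  pooled <- select_k(X, seq_len(k_max), control)
  pooled_ne <- min(pooled$table$neg_evidence, na.rm = TRUE)
  tibble::tibble(
    split_neg_evidence = split_ne,
    pooled_neg_evidence = pooled_ne,
    difference = split_ne - pooled_ne,
    split_favoured = split_ne < pooled_ne
  )
}

#' Simulate a separable two-class data set
#'
#' Convenience generator for classifier checks: two single-component
#' metacommunities with disjoint dominant taxa (80% of the mass on taxa 1-5
#' versus 6-10 of 20, theta = 50), each sampled under the default
#' library-size law.
#'
#' @param n_per_class Samples per class.
#' @param seed Integer seed.
#' @return A list with `counts` (combined tibble) and `labels` (named
#'   character vector, classes `"classA"`/`"classB"`).
#' @export
simulate_two_classes <- function(n_per_class = 25, seed = 1) {
  spec2 <- dmm_benchmark_spec("k2", seed = seed)
  specA <- dmm_sim_spec(n_per_class, spec2$means[1, ], theta = 50, seed = seed)
  specB <- dmm_sim_spec(n_per_class, spec2$means[2, ], theta = 50, seed = seed + 1L)
  simA <- dmm_simulate(specA)
  simB <- dmm_simulate(specB)
  XA <- as_count_matrix(simA$counts)
  XB <- as_count_matrix(simB$counts)
  rownames(XA) <- paste0("A_", rownames(XA))
  rownames(XB) <- paste0("B_", rownames(XB))
  X <- rbind(XA, XB)
  labels <- setNames(rep(c("classA", "classB"), each = n_per_class), rownames(X))
  list(counts = count_tbl(X), labels = labels)
}
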