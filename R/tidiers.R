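#' Tidy a fitted DMM
#'
#' @param x A [dmm_fit()].
#' @param ... Unused.
#' @return A tibble with one row per component-taxon pair: `component`,
#'   `taxon`, `lambda`, `alpha`, `mean`.
#' @export
tidy.dmm_fit <- function(x, ...) {
  k <- x$model$k
  tibble::tibble(
    component = rep(seq_len(k), each = x$model$s),
    taxon = rep(x$model$taxa, k),
    lambda = as.vector(t(x$model$lambda)),
    alpha = as.vector(t(x$model$alpha)),
    mean = as.vector(t(x$model$mean))
  )
}

#' One-row summary of a fitted DMM
#'
#' @inheritParams tidy.dmm_fit
#' @return A tibble with `k`, `n`, `s`, `neg_log_posterior`, `n_iter`,
#'   `converged`.
#' @export
glance.dmm_fit <- function(x, ...) {
  tibble::tibble(
    k = x$model$k, n = nrow(x$counts), s = x$model$s,
    neg_log_posterior = x$neg_log_posterior,
    n_iter = x$n_iter, converged = x$converged
  )
}

#' Per-sample cluster assignments with responsibilities
#'
#' @inheritParams tidy.dmm_fit
#' @param data Unused (the fit retains its counts).
#' @return [hard_assign()] output with one responsibility column per
#'   component.
#' @export
augment.dmm_fit <- function(x, data = NULL, ...) {
  out <- hard_assign(x)
  dplyr::bind_cols(out, tibble::as_tibble(x$responsibilities))
}

#' @export
tidy.dmm_select <- function(x, ...) x$table

#' @export
glance.dmm_select <- function(x, ...) {
  dplyr::filter(x$table, .data$k == x$best_k)
}

#' @export
tidy.dmm_roc <- function(x, ...) x$points

#' @export
glance.dmm_roc <- function(x, ...) tibble::tibble(auc = x$auc, positive = x$positive)

#' @export
tidy.dmm_difference <- function(x, ...) x$per_taxon

#' @export
glance.dmm_difference <- function(x, ...) {
  tibble::tibble(grand_total_pct = x$grand_total, k = nrow(x$per_component))
}

#' @export
tidy.dmm_recovery <- function(x, ...) x$per_component

#' @export
glance.dmm_recovery <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, ari = x$ari,
                 weight_l1 = x$weight_l1, k_matched = x$k_matched)
}

#' Evidence-versus-K curve
#'
#' Line plot of the negative Laplace log evidence against the number of
#' mixture components; the minimum marks the selected K.
#'
#' @param object A [select_k()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmm_select <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$k, y = .data$neg_evidence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(object$table, .data$k == object$best_k),
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = object$table$k) +
    ggplot2::labs(x = "number of Dirichlet components K",
                  y = "negative Laplace log evidence") +
    ggplot2::theme_minimal()
}

#' Component mean compositions
#'
#' Stacked-bar view of the fitted metacommunity mean compositions, showing
#' the `top_n` taxa with the largest overall mean and pooling the rest.
#'
#' @param object A [dmm_fit()].
#' @param top_n Taxa to display individually.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmm_fit <- function(object, top_n = 12, ...) {
  td <- tidy(object)
  keep <- td |>
    dplyr::summarise(total = sum(.data$mean), .by = "taxon") |>
    dplyr::arrange(dplyr::desc(.data$total)) |>
    head(top_n)
  td <- td |>
    dplyr::mutate(taxon = ifelse(.data$taxon %in% keep$taxon, .data$taxon, "other")) |>
    dplyr::summarise(mean = sum(.data$mean), .by = c("component", "taxon"))
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$component), y = .data$mean,
                                   fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "component", y = "mean relative abundance", fill = "taxon") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmm_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr_pct, y = .data$tpr_pct)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive %", y = "true positive %",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
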