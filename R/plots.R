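#' Plot item characteristic curves
#'
#' Visualizes the manual-score ICC against the marginal model implied by a
#' classifier error model for each item, the standard picture of how
#' automatic scoring flattens an item's response curve toward its error-rate
#' asymptotes.
#'
#' @param items Item parameter data frame (`item_id`, `a`, `b`, optional
#'   `c`, `d`).
#' @param error_models Optional named list of [error_rates()] or
#'   [logit_error_model()] objects keyed by `item_id`.
#' @param theta Ability grid.
#' @param D Logistic scaling constant.
#' @return A ggplot object.
#' @export
plot_icc <- function(items, error_models = NULL,
                     theta = seq(-4, 4, length.out = 161), D = 1) {
  tab <- curve_table(items, error_models, theta = theta, D = D)
  tab <- dplyr::filter(tab, .data$item_id != "_test_")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$theta, y = .data$icc,
                                    linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~item_id) +
    ggplot2::labs(x = expression(theta), y = "P(correct score)",
                  linetype = "model") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot item information curves
#'
#' @inheritParams plot_icc
#' @return A ggplot object.
#' @export
plot_information <- function(items, error_models = NULL,
                             theta = seq(-4, 4, length.out = 161), D = 1) {
  tab <- curve_table(items, error_models, theta = theta, D = D)
  tab <- dplyr::filter(tab, .data$item_id != "_test_")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$theta, y = .data$info,
                                    linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~item_id) +
    ggplot2::labs(x = expression(theta), y = "item information",
                  linetype = "model") +
    ggplot2::theme_minimal()
}

#' Plot the test standard error of measurement
#'
#' Compares the SEM of the manual-score test with that of the automatically
#' scored test under the marginal models.
#'
#' @inheritParams plot_icc
#' @return A ggplot object.
#' @export
plot_sem <- function(items, error_models = NULL,
                     theta = seq(-4, 4, length.out = 161), D = 1) {
  tab <- curve_table(items, error_models, theta = theta, D = D)
  tab <- dplyr::filter(tab, .data$item_id == "_test_")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$theta, y = .data$sem,
                                    linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = "SEM", linetype = "model") +
    ggplot2::theme_minimal()
}

#' Plot a study summary
#'
#' One panel per performance measure, estimators distinguished by color,
#' conditions on the x axis.
#'
#' @param object A `study_summary` from [run_study()].
#' @param measure One of `"bias"`, `"rmse"`, `"r"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_summary
#' @export
autoplot.study_summary <- function(object, measure = c("bias", "rmse", "r"),
                                   ...) {
  measure <- match.arg(measure)
  se_col <- paste0("mc_se_", measure)
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$n_persons), y = .data[[measure]],
    color = .data$estimator, group = .data$estimator)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[measure]] - 1.96 * .data[[se_col]],
      ymax = .data[[measure]] + 1.96 * .data[[se_col]]), width = 0.15) +
    ggplot2::facet_grid(parameter_group ~ n_items + error_balance,
                        scales = "free_y") +
    ggplot2::labs(x = "persons", y = measure) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
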