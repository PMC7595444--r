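#' Plot estimation- and prediction-error curves
#'
#' Replicate-mean error curves over the n-grid, one panel per model, with
#' estimation and prediction error distinguished by line type and the AR /
#' VAR fits by colour — the standard way to read off where the VAR curves
#' drop below the AR curves.
#'
#' @param curves An `error_curves` tibble.
#' @param models Optional vector of `model_id`s to show (default: all, which
#'   is only readable for a handful).
#' @param log_y Log-scale the error axis? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_error_curves <- function(curves, models = NULL, log_y = TRUE) {
  dat <- curves
  if (!is.null(models)) dat <- dplyr::filter(dat, .data$model_id %in% models)
  dat <- dat |>
    dplyr::filter(!is.na(.data$mean)) |>
    tidyr::separate_wider_delim("metric", "_", names = c("error_type", "fit_class")) |>
    dplyr::mutate(error_type = dplyr::recode(.data$error_type,
                                             EE = "estimation", PE = "prediction"))
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$mean,
                                          colour = .data$fit_class,
                                          linetype = .data$error_type)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model_id), scales = "free_y") +
    ggplot2::labs(x = "n (training observations)", y = "mean squared error",
                  colour = "fit", linetype = "error") +
    ggplot2::theme_minimal()
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' @export
autoplot.error_curves <- function(object, ...) plot_error_curves(object, ...)

#' Plot the weighted distribution of the crossover gap
#'
#' Histogram of the expected `n_gap = n_e - n_p` across models, weighted by
#' population probability.
#'
#' @param report A `crossing_report` from [summarize_collection()].
#' @return A ggplot object.
#' @export
plot_ngap_distribution <- function(report) {
  stopifnot(inherits(report, "crossing_report"), !is.null(report$n_gap))
  ggplot2::ggplot(report$n_gap$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$weight)) +
    ggplot2::geom_col(width = report$n_gap$histogram$upper[1] -
                        report$n_gap$histogram$lower[1]) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(n[gap] == n[e] - n[p]), y = "weight") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.crossing_report <- function(object, ...) plot_ngap_distribution(object)

#' Plot the rule-comparison curve
#'
#' Weighted mean regret difference `EE_comp` between the one-standard-error
#' rule and minimum-prediction-error selection, as a function of n, with a
#' one-Monte-Carlo-SD band. Positive values favour the 1SE rule.
#'
#' @param report A `rules_report` from [compare_rules()].
#' @return A ggplot object.
#' @export
plot_ee_comp <- function(report) {
  stopifnot(inherits(report, "rules_report"))
  ggplot2::ggplot(report$ee_comp_curve, ggplot2::aes(x = .data$n, y = .data$mean_ee_comp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ee_comp - .data$mc_sd,
                                      ymax = .data$mean_ee_comp + .data$mc_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "n (training observations)",
                  y = expression(EE[comp])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rules_report <- function(object, ...) plot_ee_comp(object)
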