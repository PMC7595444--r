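#' Model choice by minimum prediction error
#'
#' Picks the model with the lower out-of-sample prediction MSE; exact ties
#' go to the more parsimonious AR model. Vectorised.
#'
#' @param pe_ar,pe_var Prediction errors of the AR and VAR fits.
#' @return Character vector of `"AR"` / `"VAR"`.
#' @export
select_min_pe <- function(pe_ar, pe_var) {
  check_finite(pe_ar, pe_var)
  ifelse(pe_ar <= pe_var, "AR", "VAR")
}

#' Model choice by the one-standard-error rule
#'
#' Selects the simpler AR model whenever its prediction error is not more
#' than one standard error above the VAR model's prediction error, and the
#' VAR model otherwise (boundary inclusive). The standard error is the
#' standard deviation of the VAR prediction error across replicate training
#' sets. `se_reference = "best"` instead uses the SE of whichever model has
#' the lower prediction error (the classic statistical-learning
#' formulation), which requires `sd_pe_ar`.
#'
#' @param pe_ar,pe_var Prediction errors.
#' @param sd_pe_var Replicate SD of the VAR prediction error (`>= 0`).
#' @param se_reference `"var"` (default) or `"best"`.
#' @param sd_pe_ar Replicate SD of the AR prediction error; only used with
#'   `se_reference = "best"`.
#' @return Character vector of `"AR"` / `"VAR"`.
#' @export
select_1se <- function(pe_ar, pe_var, sd_pe_var, se_reference = c("var", "best"),
                       sd_pe_ar = NULL) {
  se_reference <- match.arg(se_reference)
  check_finite(pe_ar, pe_var, sd_pe_var)
  if (any(sd_pe_var < 0)) abort("`sd_pe_var` must be nonnegative.", class = "varcross_invalid_input")
  se <- if (se_reference == "var") {
    sd_pe_var
  } else {
    if (is.null(sd_pe_ar)) {
      abort('`sd_pe_ar` is required with se_reference = "best".',
            class = "varcross_invalid_input")
    }
    check_finite(sd_pe_ar)
    ifelse(pe_ar <= pe_var, sd_pe_ar, sd_pe_var)
  }
  ifelse(pe_ar <= pe_var + se, "AR", "VAR")
}

check_finite <- function(...) {
  for (v in list(...)) {
    if (any(!is.finite(v))) {
      abort("Selection inputs must be finite.", class = "varcross_invalid_input")
    }
  }
  invisible(NULL)
}

#' Estimation-error regret of a model choice
#'
#' `EE_best - EE_sel`: zero when the chosen model has the lower estimation
#' error, negative otherwise. Vectorised.
#'
#' @param choice Character vector of `"AR"` / `"VAR"`.
#' @param ee_ar,ee_var Estimation errors of the two fits.
#' @return Nonpositive numeric vector.
#' @export
ee_diff <- function(choice, ee_ar, ee_var) {
  stopifnot(all(choice %in% c("AR", "VAR")))
  sel <- ifelse(choice == "AR", ee_ar, ee_var)
  pmin(ee_ar, ee_var) - sel
}

#' Regret difference between the 1SE rule and minimum prediction error
#'
#' `EE_comp = EE_diff(1SE) - EE_diff(minPE)`: positive when the
#' one-standard-error rule picked the model with lower estimation error and
#' the minimum-prediction-error rule did not, negative in the opposite
#' case, and zero whenever the two rules agree.
#'
#' @inheritParams select_1se
#' @inheritParams ee_diff
#' @return Numeric vector.
#' @export
ee_comp <- function(pe_ar, pe_var, sd_pe_var, ee_ar, ee_var,
                    se_reference = c("var", "best"), sd_pe_ar = NULL) {
  d1 <- ee_diff(select_1se(pe_ar, pe_var, sd_pe_var, se_reference, sd_pe_ar),
                ee_ar, ee_var)
  d0 <- ee_diff(select_min_pe(pe_ar, pe_var), ee_ar, ee_var)
  d1 - d0
}

#' Compare the two selection rules across a collection
#'
#' For every (model, n) cell of the error curves, applies both rules to the
#' replicate-mean prediction errors (with the replicate SD of the VAR
#' prediction error as the standard error) and scores each rule by its
#' estimation-error regret against the replicate-mean estimation errors.
#'
#' @param curves An `error_curves` tibble covering one or more models.
#' @param weights Optional tibble `model_id`, `weight`; default uniform.
#'   Each (model, n) case inherits its model's weight, uniform over n
#'   within a model.
#' @param se_reference Passed to [select_1se()].
#' @return A list of class `rules_report`:
#'   * `outcomes`: per-(model, n) tibble with both choices, regrets,
#'     `ee_comp` and weight;
#'   * `disagreement`: weighted share of disagreement cases
#'     (`ee_comp != 0`) in which the 1SE rule did better, plus counts;
#'   * `ee_comp_curve`: per n, the weighted mean of `ee_comp` across
#'     models, its weighted SD across models (`mc_sd`) and the number of
#'     models contributing;
#'   * `per_model`: number of n values per model at which the rules
#'     disagree.
#' @export
compare_rules <- function(curves, weights = NULL, se_reference = c("var", "best")) {
  se_reference <- match.arg(se_reference)
  wide <- curves |>
    dplyr::select("model_id", "n", "metric", "mean", "sd") |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd")) |>
    dplyr::filter(
      is.finite(.data$mean_PE_AR), is.finite(.data$mean_PE_VAR),
      is.finite(.data$sd_PE_VAR), is.finite(.data$mean_EE_AR),
      is.finite(.data$mean_EE_VAR)
    )
  if (nrow(wide) == 0) {
    abort("No usable (model, n) cells in the curves.", class = "varcross_empty_summary")
  }
  if (is.null(weights)) {
    ids <- unique(wide$model_id)
    weights <- tibble::tibble(model_id = ids, weight = 1 / length(ids))
  }
  outcomes <- wide |>
    dplyr::mutate(
      choice_minpe = select_min_pe(.data$mean_PE_AR, .data$mean_PE_VAR),
      choice_1se = select_1se(.data$mean_PE_AR, .data$mean_PE_VAR, .data$sd_PE_VAR,
                              se_reference = se_reference, sd_pe_ar = .data$sd_PE_AR),
      ee_diff_minpe = ee_diff(.data$choice_minpe, .data$mean_EE_AR, .data$mean_EE_VAR),
      ee_diff_1se = ee_diff(.data$choice_1se, .data$mean_EE_AR, .data$mean_EE_VAR),
      ee_comp = .data$ee_diff_1se - .data$ee_diff_minpe
    ) |>
    dplyr::left_join(dplyr::select(weights, "model_id", "weight"), by = "model_id") |>
    dplyr::select("model_id", "n", pe_ar = "mean_PE_AR", pe_var = "mean_PE_VAR",
                  sd_pe_var = "sd_PE_VAR", ee_ar = "mean_EE_AR", ee_var = "mean_EE_VAR",
                  "choice_minpe", "choice_1se", "ee_diff_minpe", "ee_diff_1se",
                  "ee_comp", "weight")
  dis <- dplyr::filter(outcomes, .data$ee_comp != 0)
  disagreement <- tibble::tibble(
    n_cases = nrow(dis),
    n_total = nrow(outcomes),
    prop_1se_better = if (nrow(dis) > 0) {
      sum(dis$weight * (dis$ee_comp > 0)) / sum(dis$weight)
    } else NA_real_
  )
  ee_comp_curve <- outcomes |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(
      mean_ee_comp = sum(.data$weight * .data$ee_comp) / sum(.data$weight),
      mc_sd = {
        wn <- .data$weight / sum(.data$weight)
        mu <- sum(wn * .data$ee_comp)
        sqrt(sum(wn * (.data$ee_comp - mu)^2))
      },
      n_models = dplyr::n(),
      .groups = "drop"
    )
  per_model <- outcomes |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(n_disagreements = sum(.data$choice_minpe != .data$choice_1se),
                     .groups = "drop")
  structure(
    list(outcomes = outcomes, disagreement = disagreement,
         ee_comp_curve = ee_comp_curve, per_model = per_model,
         se_reference = se_reference),
    class = "rules_report"
  )
}

#' @export
print.rules_report <- function(x, ...) {
  cat("<rules_report>\n")
  if (x$disagreement$n_cases == 0) {
    cat("the two rules agree in every (model, n) case\n")
  } else {
    cat(sprintf("disagreement cases: %d of %d; 1SE rule better in %.1f%% (weighted)\n",
                x$disagreement$n_cases, x$disagreement$n_total,
                100 * x$disagreement$prop_1se_better))
  }
  pos <- dplyr::filter(x$ee_comp_curve, .data$mean_ee_comp > 0)
  if (nrow(pos) > 0) {
    cat(sprintf("mean EE_comp > 0 for n in [%d, %d]\n", min(pos$n), max(pos$n)))
  }
  invisible(x)
}

#' @export
glance.rules_report <- function(x, ...) {
  pos <- dplyr::filter(x$ee_comp_curve, .data$mean_ee_comp > 0)
  tibble::tibble(
    n_disagreement_cases = x$disagreement$n_cases,
    n_cases = x$disagreement$n_total,
    prop_1se_better = x$disagreement$prop_1se_better,
    first_positive_n = if (nrow(pos) > 0) min(pos$n) else NA_integer_,
    last_positive_n = if (nrow(pos) > 0) max(pos$n) else NA_integer_
  )
}
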