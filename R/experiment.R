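#' Configuration of the Monte-Carlo error-curve experiment
#'
#' @param n_grid Ascending integer sample sizes at which models are fitted
#'   (default `8:500`); fits use the first `n` rows of each replicate's
#'   training series (prefix design).
#' @param reps Replicate training series per model (default 100; at least 2
#'   so replicate SDs are defined).
#' @param n_test Length of the independent test series used for prediction
#'   error (default 2000).
#' @param burn_in Discarded initial steps per simulated series (default 100).
#' @param master_seed Master seed; per-model, per-replicate train and test
#'   streams are derived from it with [mix_seed()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_grid = 8:500, reps = 100, n_test = 2000,
                              burn_in = 100, master_seed = 1) {
  n_grid <- as.integer(n_grid)
  if (length(n_grid) < 1 || is.unsorted(n_grid, strictly = TRUE) || min(n_grid) < 3) {
    abort("`n_grid` must be strictly ascending integers with minimum >= 3.",
          class = "varcross_invalid_config")
  }
  if (reps < 2) {
    abort("`reps` must be >= 2: replicate standard deviations are undefined otherwise.",
          class = "varcross_invalid_config")
  }
  if (n_test < 2) abort("`n_test` must be >= 2.", class = "varcross_invalid_config")
  if (burn_in < 0) abort("`burn_in` must be >= 0.", class = "varcross_invalid_config")
  structure(
    list(n_grid = n_grid, reps = as.integer(reps), n_test = as.integer(n_test),
         burn_in = as.integer(burn_in), master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

#' Error curves for one true VAR model
#'
#' For each replicate, simulates one training series of length
#' `max(n_grid)` and one independent test series of length `n_test`; for
#' every `n` on the grid, fits the AR and VAR models to the first `n` rows
#' and records the estimation error against the true matrix and the
#' one-step prediction MSE on the test series. Curves are replicate means
#' and SDs. Sample sizes too small to fit (VAR needs `n >= p + 2`, AR
#' `n >= 3`) or with a singular lagged design are flagged unfittable and
#' excluded from that n's mean.
#'
#' Internally the prefix design is computed from cumulative lag
#' cross-products, so the full n-grid costs one pass over the series plus a
#' small linear solve per grid point; the result at `n = max(n_grid)` is
#' identical to a direct fit on the full series.
#'
#' @param model True [var_model()].
#' @param cfg An [experiment_config()].
#' @param model_id Integer identifier, used both in the output and to derive
#'   this model's seed stream.
#' @return An `error_curves` tibble in long format: `model_id`, `n`,
#'   `metric` (`EE_AR`, `EE_VAR`, `PE_AR`, `PE_VAR`), `mean`, `sd`,
#'   `n_reps_used`, `unfittable`.
#' @export
run_model_experiment <- function(model, cfg, model_id = 1L) {
  stopifnot(inherits(model, "var_model"), inherits(cfg, "experiment_config"))
  p <- model$p
  phi <- model$phi
  grid <- cfg$n_grid
  n_max <- max(grid)
  reps <- cfg$reps
  ii <- rep(seq_len(p), times = p)
  jj <- rep(seq_len(p), each = p)
  min_n_var <- p + 2
  ee_ar <- ee_var <- pe_ar <- pe_var <- matrix(NA_real_, reps, length(grid))
  for (r in seq_len(reps)) {
    train <- simulate_var_matrix(model, n_max, cfg$burn_in,
                                 seed = mix_seed(cfg$master_seed, model_id, r, 1))
    test <- simulate_var_matrix(model, cfg$n_test, cfg$burn_in,
                                seed = mix_seed(cfg$master_seed, model_id, r, 2))
    z <- train[-n_max, , drop = FALSE]
    y <- train[-1, , drop = FALSE]
    cum_zz <- apply(z[, ii, drop = FALSE] * z[, jj, drop = FALSE], 2, cumsum)
    cum_zy <- apply(z[, ii, drop = FALSE] * y[, jj, drop = FALSE], 2, cumsum)
    tl <- test[-cfg$n_test, , drop = FALSE]
    ty <- test[-1, , drop = FALSE]
    a_test <- crossprod(tl)
    b_test <- crossprod(tl, ty)
    c_test <- sum(ty^2)
    m_test <- (cfg$n_test - 1) * p
    pe_of <- function(ph) {
      (c_test - 2 * sum(ph * t(b_test)) + sum((ph %*% a_test) * ph)) / m_test
    }
    for (g in seq_along(grid)) {
      n <- grid[g]
      cc <- matrix(cum_zz[n - 1, ], p, p)
      gg <- matrix(cum_zy[n - 1, ], p, p)
      if (n >= min_n_var && rcond(cc) >= 1e-12) {
        phi_v <- t(solve(cc, gg))
        ee_var[r, g] <- mean((phi_v - phi)^2)
        pe_var[r, g] <- pe_of(phi_v)
      }
      d <- diag(cc)
      if (n >= 3 && all(d > .Machine$double.eps * n)) {
        phi_a <- diag(diag(gg) / d, nrow = p)
        ee_ar[r, g] <- mean((phi_a - phi)^2)
        pe_ar[r, g] <- pe_of(phi_a)
      }
    }
  }
  curve_tbl <- function(mat, metric) {
    tibble::tibble(
      model_id = as.integer(model_id),
      n = grid,
      metric = metric,
      mean = apply(mat, 2, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
      sd = apply(mat, 2, function(v) if (sum(!is.na(v)) < 2) NA_real_ else sd(v, na.rm = TRUE)),
      n_reps_used = apply(mat, 2, function(v) sum(!is.na(v))),
      unfittable = apply(mat, 2, function(v) all(is.na(v)))
    )
  }
  out <- dplyr::bind_rows(
    curve_tbl(ee_ar, "EE_AR"), curve_tbl(ee_var, "EE_VAR"),
    curve_tbl(pe_ar, "PE_AR"), curve_tbl(pe_var, "PE_VAR")
  )
  class(out) <- c("error_curves", class(out))
  out
}

#' Error curves for a whole model collection
#'
#' Maps [run_model_experiment()] over the rows of a `model_collection`,
#' using each row's `model_id` for its seed stream.
#'
#' @param collection A `model_collection` from [stratified_fill()], or any
#'   tibble with `model_id` and a `model` list-column.
#' @param cfg An [experiment_config()].
#' @param progress Print a progress line every 25 models? Default `FALSE`.
#' @return An `error_curves` tibble covering all models.
#' @export
run_collection <- function(collection, cfg, progress = FALSE) {
  stopifnot(all(c("model_id", "model") %in% names(collection)))
  out <- purrr::map2(collection$model, collection$model_id, function(m, id) {
    if (progress && id %% 25 == 0) message("model ", id, " / ", nrow(collection))
    run_model_experiment(m, cfg, model_id = id)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("error_curves", class(out))
  out
}

#' First sample size at which one curve strictly exceeds another
#'
#' Scans the n-grid for the smallest `n` with `a(n) > b(n)`; with
#' `window > 1` the exceedance must hold for `window` consecutive usable
#' grid points (sensitivity option). Entries where either curve is
#' unavailable (`NA` or flagged via `skip`) are ignored.
#'
#' @param a,b Numeric vectors aligned to `n_grid`.
#' @param n_grid Integer sample sizes.
#' @param skip Optional logical vector: `TRUE` entries are excluded.
#' @param window Number of consecutive grid points the crossing must hold
#'   for (default 1, the plain first crossing).
#' @return The crossing `n`, or `NA_integer_` if the curves never cross
#'   (censored).
#' @export
crossing_n <- function(a, b, n_grid, skip = NULL, window = 1) {
  if (length(a) != length(b) || length(a) != length(n_grid)) {
    abort("`a`, `b` and `n_grid` must have equal length.", class = "varcross_length_error")
  }
  use <- !is.na(a) & !is.na(b)
  if (!is.null(skip)) use <- use & !skip
  a <- a[use]; b <- b[use]; n <- n_grid[use]
  if (length(a) == 0) return(NA_integer_)
  exceed <- a > b
  if (window <= 1) {
    i <- which(exceed)[1]
    return(if (is.na(i)) NA_integer_ else as.integer(n[i]))
  }
  runs <- rle(exceed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- which(runs$values & runs$lengths >= window)
  if (length(ok) == 0) return(NA_integer_)
  as.integer(n[starts[ok[1]]])
}

#' Crossover sample sizes from error curves
#'
#' For each model: `n_e` is the first `n` at which the mean estimation
#' error of the AR fit strictly exceeds that of the VAR fit (the sample
#' size from which the VAR model outperforms the AR model), `n_p` the same
#' for prediction error, and `n_gap = n_e - n_p`. A crossing that never
#' happens on the grid is censored (`NA`), and `n_gap` is censored unless
#' both crossings exist.
#'
#' @param curves An `error_curves` tibble (one or many models).
#' @param window Passed to [crossing_n()].
#' @return A tibble with columns `model_id`, `n_e`, `n_p`, `n_gap`,
#'   `n_e_censored`, `n_p_censored`, `n_gap_censored`.
#' @export
crossing_summary <- function(curves, window = 1) {
  wide <- curves |>
    dplyr::select("model_id", "n", "metric", "mean", "unfittable") |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "unfittable"))
  wide |>
    dplyr::group_by(.data$model_id) |>
    dplyr::arrange(.data$n, .by_group = TRUE) |>
    dplyr::summarise(
      n_e = crossing_n(.data$mean_EE_AR, .data$mean_EE_VAR, .data$n,
                       skip = .data$unfittable_EE_AR | .data$unfittable_EE_VAR,
                       window = window),
      n_p = crossing_n(.data$mean_PE_AR, .data$mean_PE_VAR, .data$n,
                       skip = .data$unfittable_PE_AR | .data$unfittable_PE_VAR,
                       window = window),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_gap = .data$n_e - .data$n_p,
      n_e_censored = is.na(.data$n_e),
      n_p_censored = is.na(.data$n_p),
      n_gap_censored = is.na(.data$n_gap)
    )
}

#' Weighted median and quantiles (lower interpolation)
#'
#' The weighted quantile at probability `q` is the smallest observed value
#' whose cumulative normalised weight reaches `q`. With integer-valued
#' crossings this always returns an attained grid value.
#'
#' @param x Numeric values.
#' @param w Nonnegative weights (need not be normalised).
#' @param probs Probabilities.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(q) x[which(cw >= q - 1e-12)[1]], numeric(1))
}

weighted_moments <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  m3 <- sum(w * (x - mu)^3)
  list(mean = mu, var = m2, skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_)
}

weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Distribution report over a collection's crossing summaries
#'
#' Weighted summary of the crossover sample sizes across models: quantiles
#' of `n_e`, the weighted histogram, skewness and mode bin of `n_gap`, and
#' weighted Pearson correlations of `n_gap` with the model characteristics
#' `D` and `O` and with the crossing location `n_e`. Censored models are
#' excluded from each statistic (weights renormalised) and counted.
#'
#' @param summaries A [crossing_summary()] tibble; if it carries `D` and `O`
#'   columns (e.g. after joining the collection manifest) correlations with
#'   them are reported.
#' @param weights Optional tibble `model_id`, `weight` (e.g. from
#'   [model_weights()]); default uniform.
#' @param gap_binwidth Histogram bin width for `n_gap`; bins are centred so
#'   one bin is centred at 0. The default (`NULL`) uses the lattice spacing
#'   of the observed values (the n-grid step), so every bin covers the same
#'   number of attainable values.
#' @return A list of class `crossing_report`: `n_e` (quantiles), `n_gap`
#'   (moments, mode, histogram tibble), `correlations`, `censoring`.
#' @export
summarize_collection <- function(summaries, weights = NULL, gap_binwidth = NULL) {
  s <- tibble::as_tibble(summaries)
  if (!is.null(weights)) {
    s$weight <- NULL
    s <- dplyr::left_join(s, dplyr::select(tibble::as_tibble(weights), "model_id", "weight"),
                          by = "model_id")
  } else if (!"weight" %in% names(s)) {
    s$weight <- 1 / nrow(s)
  }
  se <- dplyr::filter(s, !.data$n_e_censored)
  if (nrow(se) == 0) {
    abort("No uncensored n_e values to summarise.", class = "varcross_empty_summary")
  }
  ne_q <- weighted_quantile(se$n_e, se$weight, c(0.25, 0.5, 0.75))
  sg <- dplyr::filter(s, !.data$n_gap_censored)
  gap <- NULL
  if (nrow(sg) > 0) {
    mom <- weighted_moments(sg$n_gap, sg$weight)
    if (is.null(gap_binwidth)) {
      u <- sort(unique(sg$n_gap))
      gap_binwidth <- if (length(u) > 1) min(diff(u)) else 1
    }
    half <- gap_binwidth / 2
    lo <- floor((min(sg$n_gap) + half) / gap_binwidth) * gap_binwidth - half
    breaks <- seq(lo, max(sg$n_gap) + gap_binwidth, by = gap_binwidth)
    bin <- findInterval(sg$n_gap, breaks, rightmost.closed = TRUE)
    hist <- tibble::tibble(bin = bin, w = sg$weight / sum(sg$weight)) |>
      dplyr::count(.data$bin, wt = .data$w, name = "weight") |>
      dplyr::mutate(
        lower = breaks[.data$bin], upper = breaks[.data$bin + 1],
        mid = (.data$lower + .data$upper) / 2
      )
    mode_row <- hist[which.max(hist$weight), ]
    gap <- list(
      mean = mom$mean, skewness = mom$skewness,
      mode_bin = c(lower = mode_row$lower, upper = mode_row$upper, mid = mode_row$mid),
      histogram = dplyr::select(hist, "lower", "mid", "upper", "weight")
    )
  }
  correlations <- tibble::tibble(
    variable = c("D", "O", "n_e"),
    cor_with_n_gap = c(
      if ("D" %in% names(sg)) weighted_cor(sg$n_gap, sg$D, sg$weight) else NA_real_,
      if ("O" %in% names(sg)) weighted_cor(sg$n_gap, sg$O, sg$weight) else NA_real_,
      if (nrow(sg) > 0) weighted_cor(sg$n_gap, sg$n_e, sg$weight) else NA_real_
    )
  )
  structure(
    list(
      n_e = tibble::tibble(q25 = ne_q[1], median = ne_q[2], q75 = ne_q[3]),
      n_gap = gap,
      correlations = correlations,
      censoring = tibble::tibble(
        n_models = nrow(s),
        n_e_censored = sum(s$n_e_censored),
        n_p_censored = sum(s$n_p_censored),
        n_gap_censored = sum(s$n_gap_censored)
      )
    ),
    class = "crossing_report"
  )
}

#' @export
print.crossing_report <- function(x, ...) {
  cat("<crossing_report>\n")
  cat(sprintf("n_e: median %s (IQR %s-%s); %d/%d models censored\n",
              x$n_e$median, x$n_e$q25, x$n_e$q75,
              x$censoring$n_e_censored, x$censoring$n_models))
  if (!is.null(x$n_gap)) {
    cat(sprintf("n_gap: mean %.1f, skewness %.2f, mode bin [%g, %g]\n",
                x$n_gap$mean, x$n_gap$skewness,
                x$n_gap$mode_bin["lower"], x$n_gap$mode_bin["upper"]))
  }
  invisible(x)
}

#' @export
glance.crossing_report <- function(x, ...) {
  tibble::tibble(
    n_models = x$censoring$n_models,
    median_n_e = x$n_e$median,
    q25_n_e = x$n_e$q25,
    q75_n_e = x$n_e$q75,
    n_e_censored = x$censoring$n_e_censored,
    mean_n_gap = if (!is.null(x$n_gap)) x$n_gap$mean else NA_real_,
    skewness_n_gap = if (!is.null(x$n_gap)) x$n_gap$skewness else NA_real_,
    mode_n_gap = if (!is.null(x$n_gap)) unname(x$n_gap$mode_bin["mid"]) else NA_real_,
    cor_n_gap_D = x$correlations$cor_with_n_gap[1],
    cor_n_gap_O = x$correlations$cor_with_n_gap[2],
    cor_n_gap_n_e = x$correlations$cor_with_n_gap[3]
  )
}
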