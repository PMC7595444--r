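#' Construct a VAR(1) data-generating process
#'
#' A first-order vector autoregression \eqn{x_t = \Phi x_{t-1} + \epsilon_t}
#' with a diagonal innovation covariance. The transition matrix `phi` holds
#' the autoregressive effects on its diagonal and the cross-lagged effects
#' off the diagonal.
#'
#' @param phi Square numeric matrix of lag-1 coefficients.
#' @param noise_vars Positive numeric vector of innovation variances, one per
#'   variable (the diagonal of the error covariance). Defaults to unit
#'   variances.
#' @param check_stationary If `TRUE` (default), error unless all eigenvalues
#'   of `phi` lie strictly inside the unit circle.
#' @return An object of class `var_model` with elements `phi`, `noise_vars`
#'   and `p`.
#' @examples
#' m <- var_model(diag(0.5, 3))
#' m
#' @export
var_model <- function(phi, noise_vars = rep(1, nrow(phi)), check_stationary = TRUE) {
  phi <- as.matrix(phi)
  check_phi_matrix(phi)
  p <- nrow(phi)
  if (length(noise_vars) != p || any(!is.finite(noise_vars)) || any(noise_vars <= 0)) {
    abort("`noise_vars` must be a length-p vector of strictly positive finite values.",
          class = "varcross_invalid_model")
  }
  if (check_stationary && !is_stationary(phi)) {
    abort("`phi` is not stationary: its spectral radius is >= 1.",
          class = "varcross_nonstationary")
  }
  structure(
    list(phi = unname(phi), noise_vars = as.numeric(noise_vars), p = p),
    class = "var_model"
  )
}

#' @export
print.var_model <- function(x, ...) {
  ch <- characteristics(x)
  cat(sprintf("<var_model> p = %d, D = %.3f, O = %.3f\n", x$p, ch$D, ch$O))
  cat("phi:\n")
  print(round(x$phi, 3))
  cat("noise variances:", paste(signif(x$noise_vars, 3), collapse = ", "), "\n")
  invisible(x)
}

check_phi_matrix <- function(phi) {
  if (!is.matrix(phi) || nrow(phi) != ncol(phi) || nrow(phi) < 1 ||
      !is.numeric(phi) || any(!is.finite(phi))) {
    abort("`phi` must be a square numeric matrix with finite entries.",
          class = "varcross_invalid_matrix")
  }
  invisible(phi)
}

#' Is a transition matrix stationary?
#'
#' A VAR(1) process is (covariance-)stationary iff every eigenvalue of its
#' transition matrix has modulus strictly below 1.
#'
#' @param phi Square numeric matrix, or a [var_model()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_stationary(diag(0.5, 6)) # TRUE
#' is_stationary(diag(6))      # FALSE: |lambda| = 1 is not < 1
#' @export
is_stationary <- function(phi) {
  if (inherits(phi, "var_model")) phi <- phi$phi
  phi <- as.matrix(phi)
  check_phi_matrix(phi)
  max(Mod(eigen(phi, only.values = TRUE)$values)) < 1
}

#' Transition-matrix characteristics D and O
#'
#' Summarises a lag-1 coefficient matrix by the mean absolute autoregressive
#' effect \eqn{D = \frac{1}{p}\sum_i |\Phi_{ii}|} and the mean absolute
#' cross-lagged effect \eqn{O = \frac{1}{p(p-1)}\sum_{i \ne j} |\Phi_{ij}|}.
#' For a univariate model `O` is defined as 0 (there are no off-diagonal
#' cells).
#'
#' @param x Square numeric matrix or a [var_model()].
#' @return A one-row tibble with columns `D` and `O`.
#' @examples
#' characteristics(matrix(c(0.5, 0.1, 0.2, 0.3), 2, byrow = TRUE)) # D = 0.4, O = 0.15
#' @export
characteristics <- function(x) {
  if (inherits(x, "var_model")) x <- x$phi
  phi <- as.matrix(x)
  check_phi_matrix(phi)
  p <- nrow(phi)
  d <- mean(abs(diag(phi)))
  o <- if (p == 1) 0 else sum(abs(phi)[row(phi) != col(phi)]) / (p * (p - 1))
  tibble::tibble(D = d, O = o)
}

#' Simulate a time series from a VAR(1) model
#'
#' Generates `n` observations of \eqn{x_t = \Phi x_{t-1} + \epsilon_t} with
#' independent Gaussian innovations (variance `noise_vars[i]` in coordinate
#' i), starting from the zero state and discarding `burn_in` initial steps so
#' the retained series is (approximately) a draw from the stationary
#' distribution. The series is zero-mean by construction; no intercept is
#' simulated.
#'
#' @param model A [var_model()].
#' @param n Number of retained observations (`n >= 2`).
#' @param burn_in Number of discarded initial steps (default 100).
#' @param seed Optional integer seed; identical `(model, n, burn_in, seed)`
#'   give bit-identical output.
#' @return A tibble with `n` rows and columns `V1 ... Vp`; row t is time
#'   point t.
#' @examples
#' m <- var_model(diag(0.5, 2))
#' ts <- simulate_var(m, n = 100, seed = 1)
#' head(ts)
#' @export
simulate_var <- function(model, n, burn_in = 100, seed = NULL) {
  stopifnot(inherits(model, "var_model"))
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    abort("`n` must be a single integer >= 2.", class = "varcross_size_error")
  }
  if (!is_stationary(model$phi)) {
    abort("Cannot simulate from a non-stationary model.", class = "varcross_nonstationary")
  }
  x <- simulate_var_matrix(model, n, burn_in, seed)
  tibble::as_tibble(as.data.frame(x))
}

# Matrix-returning simulation core shared by simulate_var() and the
# experiment driver (which avoids tibble overhead in its inner loop).
simulate_var_matrix <- function(model, n, burn_in = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- model$p
  phi <- model$phi
  total <- burn_in + n
  eps <- matrix(rnorm(total * p), nrow = total, ncol = p)
  eps <- sweep(eps, 2, sqrt(model$noise_vars), `*`)
  out <- matrix(0, nrow = n, ncol = p)
  x <- numeric(p)
  for (t in seq_len(total)) {
    x <- drop(phi %*% x) + eps[t, ]
    if (t > burn_in) out[t - burn_in, ] <- x
  }
  colnames(out) <- paste0("V", seq_len(p))
  out
}

as_series_matrix <- function(ts) {
  if (is.matrix(ts)) {
    x <- ts
  } else if (is.data.frame(ts)) {
    x <- as.matrix(ts)
  } else {
    abort("A time series must be a numeric matrix or data frame.",
          class = "varcross_invalid_series")
  }
  if (!is.numeric(x) || any(!is.finite(x)) || nrow(x) < 2) {
    abort("A time series must be numeric, finite, with at least 2 rows.",
          class = "varcross_invalid_series")
  }
  x
}

#' Wrap a coefficient matrix as a fit object
#'
#' Lets an arbitrary lag-1 coefficient matrix — e.g. the true transition
#' matrix, or a hand-constructed one — be evaluated with
#' [estimation_error()] and [prediction_error()] alongside estimated fits.
#'
#' @param phi_hat Square numeric matrix of lag-1 coefficients.
#' @param model_class `"VAR"` (default) or `"AR"`; an AR fit must be
#'   diagonal.
#' @param n_used Nominal sample size to record (default `NA`).
#' @return A `var_fit`.
#' @examples
#' truth <- var_model(diag(0.5, 2))
#' fit <- var_fit(truth$phi)
#' estimation_error(fit, truth) # 0
#' @export
var_fit <- function(phi_hat, model_class = c("VAR", "AR"), n_used = NA_integer_) {
  model_class <- match.arg(model_class)
  phi_hat <- as.matrix(phi_hat)
  check_phi_matrix(phi_hat)
  if (model_class == "AR" && any(phi_hat[row(phi_hat) != col(phi_hat)] != 0)) {
    abort("An AR fit must have a diagonal coefficient matrix.",
          class = "varcross_invalid_model")
  }
  new_var_fit(phi_hat, model_class, n_used)
}

new_var_fit <- function(phi_hat, model_class, n_used, intercept = NULL) {
  structure(
    list(phi_hat = unname(phi_hat), model_class = model_class,
         n_used = as.integer(n_used), intercept = intercept),
    class = "var_fit"
  )
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> %s fit, p = %d, n = %d\n",
              x$model_class, nrow(x$phi_hat), x$n_used))
  print(round(x$phi_hat, 3))
  invisible(x)
}

#' Fit a VAR(1) model by per-equation ordinary least squares
#'
#' Regresses \eqn{x_t} on \eqn{x_{t-1}} (t = 2..n) equation by equation.
#' Series are assumed zero-mean and no intercept is fitted by default, which
#' matches how [simulate_var()] generates data; set `intercept = TRUE` for
#' non-centred data (the intercept is estimated but not part of `phi_hat`).
#'
#' @param ts Time series: numeric matrix or data frame, rows are time points.
#' @param intercept Fit a per-equation intercept? Default `FALSE`.
#' @return A `var_fit` with the full `p x p` coefficient matrix `phi_hat`,
#'   `model_class = "VAR"` and `n_used = nrow(ts)`.
#' @seealso [fit_ar()], [estimation_error()], [prediction_error()]
#' @export
fit_var <- function(ts, intercept = FALSE) {
  x <- as_series_matrix(ts)
  n <- nrow(x)
  p <- ncol(x)
  need <- p + 1 + as.integer(intercept)
  if (n < need) {
    abort(sprintf("VAR fit needs n >= %d rows for p = %d; got n = %d.", need, p, n),
          class = "varcross_size_error")
  }
  lag <- x[-n, , drop = FALSE]
  y <- x[-1, , drop = FALSE]
  design <- if (intercept) cbind(1, lag) else lag
  cp <- crossprod(design)
  if (rcond(cp) < 1e-12) {
    abort(sprintf("Singular lagged design (n_used = %d, p = %d): condition number > 1e12.", n, p),
          class = "varcross_singular_design", n_used = n, p = p)
  }
  beta <- solve(cp, crossprod(design, y))
  if (intercept) {
    phi_hat <- t(beta[-1, , drop = FALSE])
    new_var_fit(phi_hat, "VAR", n, intercept = as.numeric(beta[1, ]))
  } else {
    new_var_fit(t(beta), "VAR", n)
  }
}

#' Fit an AR(1) model (diagonal transition matrix)
#'
#' Each variable is predicted only by its own previous value: entry i of the
#' diagonal is the univariate least-squares slope of \eqn{x_{t,i}} on
#' \eqn{x_{t-1,i}}. Off-diagonal entries of the returned matrix are exactly
#' zero, so estimation and prediction errors of AR and VAR fits are directly
#' comparable on the full coefficient matrix.
#'
#' @inheritParams fit_var
#' @return A `var_fit` with diagonal `phi_hat` and `model_class = "AR"`.
#' @export
fit_ar <- function(ts, intercept = FALSE) {
  x <- as_series_matrix(ts)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3) {
    abort(sprintf("AR fit needs n >= 3 rows; got n = %d.", n),
          class = "varcross_size_error")
  }
  lag <- x[-n, , drop = FALSE]
  y <- x[-1, , drop = FALSE]
  if (intercept) {
    lag <- scale(lag, scale = FALSE)
    mu_y <- colMeans(y)
    y <- sweep(y, 2, mu_y, `-`)
  }
  denom <- colSums(lag^2)
  if (any(denom <= .Machine$double.eps * n)) {
    abort("Constant column: zero lagged variance makes the AR slope undefined.",
          class = "varcross_singular_design", n_used = n, p = p)
  }
  slopes <- colSums(lag * y) / denom
  phi_hat <- diag(slopes, nrow = p)
  icpt <- if (intercept) mu_y - slopes * attr(lag, "scaled:center") else NULL
  new_var_fit(phi_hat, "AR", n, intercept = icpt)
}

#' Estimation error of a fitted transition matrix
#'
#' Mean squared deviation between the estimated and the true lag-1
#' coefficient matrix, averaged over all \eqn{p^2} entries. For AR fits the
#' structural zeros count: each true cross-lagged effect enters as
#' \eqn{(0 - \Phi_{ij})^2}, which is the bias the AR model pays for ignoring
#' cross-lagged dynamics.
#'
#' @param fit A `var_fit`.
#' @param truth The generating [var_model()].
#' @return A single nonnegative number.
#' @export
estimation_error <- function(fit, truth) {
  stopifnot(inherits(fit, "var_fit"), inherits(truth, "var_model"))
  if (!identical(dim(fit$phi_hat), dim(truth$phi))) {
    abort("Dimension mismatch between fit and truth.", class = "varcross_dim_error")
  }
  mean((fit$phi_hat - truth$phi)^2)
}

#' One-step-ahead prediction error on a test series
#'
#' Mean squared error of the predictions \eqn{\hat\Phi x_{t-1}} against the
#' observed \eqn{x_t} over t = 2..n of an independent test series, averaged
#' over both time points and coordinates (a single scalar MSE).
#'
#' @param fit A `var_fit`.
#' @param test Test series: numeric matrix or data frame.
#' @return A single nonnegative number; for the true model on a long test
#'   series it approaches the mean innovation variance (the irreducible
#'   error).
#' @export
prediction_error <- function(fit, test) {
  stopifnot(inherits(fit, "var_fit"))
  x <- as_series_matrix(test)
  if (ncol(x) != nrow(fit$phi_hat)) {
    abort("Dimension mismatch between fit and test series.", class = "varcross_dim_error")
  }
  n <- nrow(x)
  pred <- x[-n, , drop = FALSE] %*% t(fit$phi_hat)
  if (!is.null(fit$intercept)) pred <- sweep(pred, 2, fit$intercept, `+`)
  mean((x[-1, , drop = FALSE] - pred)^2)
}

#' @export
tidy.var_fit <- function(x, ...) {
  p <- nrow(x$phi_hat)
  tidyr::expand_grid(response = seq_len(p), predictor = seq_len(p)) |>
    dplyr::mutate(
      term = paste0("phi[", .data$response, ",", .data$predictor, "]"),
      estimate = purrr::map2_dbl(.data$response, .data$predictor, ~ x$phi_hat[.x, .y])
    ) |>
    dplyr::select("term", "response", "predictor", "estimate")
}

#' @export
glance.var_fit <- function(x, ...) {
  tibble::tibble(
    model_class = x$model_class,
    p = nrow(x$phi_hat),
    n_used = x$n_used,
    intercept = !is.null(x$intercept)
  )
}
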