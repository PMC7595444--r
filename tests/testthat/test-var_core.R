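test_that("stationarity is the strict unit-circle criterion", {
  expect_true(is_stationary(diag(0.5, 6)))
  expect_false(is_stationary(diag(6))) # |lambda| = 1 is not strictly < 1
  # rank-1 symmetric matrix with eigenvalues 1.8 and 0
  expect_false(is_stationary(matrix(0.9, 2, 2)))
  expect_error(is_stationary(matrix(1:6, 2, 3)), class = "varcross_invalid_matrix")
  expect_error(is_stationary(matrix(c(1, NA, 0, 1), 2)), class = "varcross_invalid_matrix")
})

test_that("D and O are mean absolute diagonal and off-diagonal effects", {
  expect_equal(characteristics(diag(6)), tibble::tibble(D = 1, O = 0))
  expect_equal(characteristics(matrix(0, 6, 6)), tibble::tibble(D = 0, O = 0))
  expect_equal(
    characteristics(matrix(c(0.5, 0.2, 0.1, 0.3), 2, byrow = TRUE)),
    tibble::tibble(D = 0.4, O = 0.15)
  )
  # signs do not cancel
  expect_equal(characteristics(matrix(c(-0.5, -0.2, 0.2, 0.5), 2))$O, 0.2)
})

test_that("var_model validates its invariants", {
  expect_error(var_model(diag(2), check_stationary = TRUE),
               class = "varcross_nonstationary")
  expect_error(var_model(diag(0.5, 2), noise_vars = c(1, -1)),
               class = "varcross_invalid_model")
  m <- var_model(matrix(0.5, 1, 1)) # univariate models are allowed
  expect_equal(m$p, 1)
})

test_that("simulation is deterministic in the seed and matches white noise", {
  m <- var_model(diag(0.4, 3))
  a <- simulate_var(m, 50, burn_in = 10, seed = 42)
  b <- simulate_var(m, 50, burn_in = 10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_var(m, 50, burn_in = 10, seed = 43)))

  wn <- var_model(matrix(0, 2, 2), check_stationary = TRUE)
  x <- as.matrix(simulate_var(wn, 10000, seed = 7))
  ac1 <- vapply(1:2, function(j) cor(x[-1, j], x[-nrow(x), j]), numeric(1))
  expect_lt(max(abs(ac1)), 0.05)
})

test_that("simulated stationary variance matches the AR(1) closed form", {
  # small-n version; the n = 50000 check lives in the acceptance suite
  m <- var_model(matrix(0.5, 1, 1))
  x <- as.matrix(simulate_var(m, 20000, seed = 11))
  expect_equal(var(x[, 1]), 1 / (1 - 0.25), tolerance = 0.05)
})

test_that("noise-free series are interpolated exactly", {
  phi <- rand_stationary_phi(3, seed = 5)
  # deterministic recursion from a random start; lags span R^3 generically
  set.seed(5)
  x <- matrix(0, 12, 3)
  x[1, ] <- rnorm(3)
  for (t in 2:12) x[t, ] <- phi %*% x[t - 1, ]
  fit <- fit_var(x)
  expect_lt(max(abs(fit$phi_hat - phi)), 1e-10)

  phi_d <- diag(c(0.6, -0.3, 0.2))
  xd <- matrix(0, 12, 3)
  xd[1, ] <- c(1, -2, 0.5)
  for (t in 2:12) xd[t, ] <- phi_d %*% xd[t - 1, ]
  fit_d <- fit_ar(xd)
  expect_lt(max(abs(fit_d$phi_hat - phi_d)), 1e-10)
})

test_that("least-squares fits agree with a brute-force numerical minimizer", {
  m <- var_model(rand_stationary_phi(3, seed = 2))
  x <- as.matrix(simulate_var(m, 12, seed = 3))
  expect_lt(max(abs(fit_var(x)$phi_hat - brute_force_ls(x))), 1e-8)
  expect_lt(max(abs(fit_ar(x)$phi_hat - brute_force_ls(x, diagonal = TRUE))), 1e-8)
})

test_that("VAR estimates are consistent: error shrinks with n", {
  phi <- constant_do_phi(4, 0.3, 0.05)
  m <- var_model(phi)
  errs <- vapply(1:50, function(r) {
    x <- as.matrix(simulate_var(m, 500, seed = mix_seed(77, r)))
    c(estimation_error(fit_var(x[1:50, ]), m), estimation_error(fit_var(x), m))
  }, numeric(2))
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("AR fits are diagonal and converge to lag-1 autocorrelations, not phi", {
  phi <- matrix(c(0.2, 0.5, 0.5, 0.2), 2) # strong cross-lags
  m <- var_model(phi)
  x <- as.matrix(simulate_var(m, 50000, seed = 9))
  fit <- fit_ar(x)
  expect_true(all(fit$phi_hat[row(fit$phi_hat) != col(fit$phi_hat)] == 0))
  ac1 <- vapply(1:2, function(j) {
    sum(x[-1, j] * x[-nrow(x), j]) / sum(x[-nrow(x), j]^2)
  }, numeric(1))
  expect_equal(diag(fit$phi_hat), ac1, tolerance = 1e-10)
  # the autocorrelation is far from the diagonal of phi here
  expect_gt(min(abs(ac1 - diag(phi))), 0.1)
})

test_that("estimation error averages squared deviations over all p^2 entries", {
  truth <- var_model(matrix(c(0.5, 0.1, 0.2, 0.3), 2, byrow = TRUE))
  expect_equal(estimation_error(var_fit(truth$phi), truth), 0)
  expect_equal(estimation_error(var_fit(truth$phi + 0.1), truth), 0.01)
  # structural zeros of an all-zero fit are penalised
  expect_equal(estimation_error(var_fit(matrix(0, 2, 2)), truth),
               (0.25 + 0.04 + 0.01 + 0.09) / 4)
  expect_error(estimation_error(var_fit(diag(0.5, 3)), truth),
               class = "varcross_dim_error")
})

test_that("prediction error is the grand-mean one-step MSE", {
  phi <- rand_stationary_phi(2, seed = 4)
  x <- matrix(0, 20, 2)
  x[1, ] <- c(1, -1)
  for (t in 2:20) x[t, ] <- phi %*% x[t - 1, ]
  expect_equal(prediction_error(var_fit(phi), x), 0)
  # zero fit predicts the zero vector
  expect_equal(prediction_error(var_fit(matrix(0, 2, 2)), x), mean(x[-1, ]^2))

  m <- var_model(phi, noise_vars = c(1, 2))
  test <- simulate_var(m, 20000, seed = 8)
  expect_equal(prediction_error(var_fit(phi), test), 1.5, tolerance = 0.05)
})

test_that("prediction error of any fit is bounded below by the noise floor", {
  m <- var_model(constant_do_phi(3, 0.3, 0.06), noise_vars = c(0.5, 1, 1.5))
  test <- simulate_var(m, 5000, seed = 21)
  for (n in c(10, 50, 200)) {
    train <- simulate_var(m, n, seed = mix_seed(22, n))
    expect_gt(prediction_error(fit_var(train), test), mean(m$noise_vars) - 0.15)
    expect_gt(prediction_error(fit_ar(train), test), mean(m$noise_vars) - 0.15)
  }
})

test_that("degenerate designs raise singular-design errors", {
  # an all-zero column has zero lagged variance in the no-intercept fit
  set.seed(2)
  zero_col <- cbind(rnorm(10), 0)
  expect_error(fit_ar(zero_col), class = "varcross_singular_design")
  # a constant column is degenerate once centred by the intercept fit
  expect_error(fit_ar(matrix(1, 10, 2), intercept = TRUE),
               class = "varcross_singular_design")
  # duplicated column makes the lagged design rank deficient
  set.seed(1)
  v <- rnorm(10)
  expect_error(fit_var(cbind(v, v)), class = "varcross_singular_design")
  expect_error(fit_var(matrix(rnorm(6), 2, 3)), class = "varcross_size_error")
})

test_that("intercept fitting recovers a nonzero mean without entering phi_hat", {
  m <- var_model(diag(c(0.5, 0.3)))
  x <- as.matrix(simulate_var(m, 4000, seed = 13))
  shifted <- sweep(x, 2, c(5, -3), `+`)
  fv <- fit_var(shifted, intercept = TRUE)
  fa <- fit_ar(shifted, intercept = TRUE)
  expect_equal(dim(fv$phi_hat), c(2, 2))
  expect_equal(fv$phi_hat, m$phi, tolerance = 0.1)
  expect_equal(diag(fa$phi_hat), diag(m$phi), tolerance = 0.1)
  # fitted means: intercept / (1 - phi) approximates the shift
  expect_equal(fv$intercept / (1 - diag(fv$phi_hat)), c(5, -3), tolerance = 0.2)
  expect_lt(prediction_error(fv, shifted), 2)
})

test_that("model CSV round-trips exactly and series I/O keeps the header", {
  m <- var_model(rand_stationary_phi(4, seed = 6), noise_vars = exp(rnorm(4) / 3))
  path <- tempfile(fileext = ".csv")
  write_var_model(m, path)
  m2 <- read_var_model(path)
  expect_identical(m2$phi, m$phi)
  expect_identical(m2$noise_vars, m$noise_vars)

  ts <- simulate_var(m, 20, seed = 1)
  sp <- tempfile(fileext = ".csv")
  write_series(ts, sp)
  back <- read_series(sp)
  expect_equal(names(back), paste0("V", 1:4))
  expect_equal(as.matrix(back), as.matrix(ts), tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom shape", {
  m <- var_model(diag(0.4, 2))
  fit <- fit_var(simulate_var(m, 100, seed = 3))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_named(td, c("term", "response", "predictor", "estimate"))
  expect_equal(td$estimate[td$response == 2 & td$predictor == 1], fit$phi_hat[2, 1])
  gl <- glance(fit)
  expect_equal(gl$model_class, "VAR")
  expect_equal(gl$n_used, 100L)
})
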