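# Shared fixtures and independent oracles, built in code at test time.

# Generic numerical least-squares oracle: minimises the residual sum of
# squares of x_t on x_{t-1} with BFGS (analytic gradient, quadratic
# objective), independently of the normal-equations path in fit_var/fit_ar.
# Returns the p x p coefficient matrix (diagonal when diagonal = TRUE).
brute_force_ls <- function(x, diagonal = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  l <- x[-n, , drop = FALSE]
  y <- x[-1, , drop = FALSE]
  if (diagonal) {
    f <- function(par) sum((y - l %*% diag(par, p))^2)
    g <- function(par) -2 * colSums(l * (y - l %*% diag(par, p)))
    par <- rep(0, p)
  } else {
    f <- function(par) sum((y - l %*% matrix(par, p, p))^2)
    g <- function(par) as.numeric(-2 * crossprod(l, y - l %*% matrix(par, p, p)))
    par <- numeric(p * p)
  }
  for (k in 1:2) { # second pass polishes to machine precision
    res <- stats::optim(par, f, g, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    par <- res$par
  }
  if (diagonal) diag(par, p) else t(matrix(par, p, p))
}

# A random stationary transition matrix (rejection sampled).
rand_stationary_phi <- function(p, seed, diag_sd = 0.3, off_sd = 0.15) {
  set.seed(seed)
  repeat {
    phi <- matrix(rnorm(p * p, 0, off_sd), p, p)
    diag(phi) <- rnorm(p, 0.2, diag_sd)
    if (is_stationary(phi)) return(phi)
  }
}

# Transition matrix with constant diagonal d and constant off-diagonal o,
# so that D = |d| and O = |o| exactly.
constant_do_phi <- function(p, d, o) {
  phi <- matrix(o, p, p)
  diag(phi) <- d
  phi
}

# Long-format error-curves tibble assembled by hand, for tests that need
# fully controlled selection inputs: one row per metric per model per n.
manual_curves <- function(df) {
  # df: tibble with model_id, n, ee_ar, ee_var, pe_ar, pe_var, sd_pe_var
  out <- dplyr::bind_rows(
    dplyr::transmute(df, model_id, n, metric = "EE_AR", mean = ee_ar, sd = 0),
    dplyr::transmute(df, model_id, n, metric = "EE_VAR", mean = ee_var, sd = 0),
    dplyr::transmute(df, model_id, n, metric = "PE_AR", mean = pe_ar, sd = 0),
    dplyr::transmute(df, model_id, n, metric = "PE_VAR", mean = pe_var, sd = sd_pe_var)
  )
  out$n_reps_used <- 2L
  out$unfittable <- FALSE
  out
}
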