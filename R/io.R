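#' Read and write VAR models as plain-text CSV
#'
#' A model is stored as a `(p + 1) x p` CSV with header `V1 ... Vp`: the
#' first `p` rows are the transition matrix, the final row the innovation
#' variances. Values round-trip exactly (written with 17 significant
#' digits).
#'
#' @param model A [var_model()].
#' @param path File path.
#' @return `write_var_model()` returns `path` invisibly; `read_var_model()`
#'   returns a [var_model()].
#' @export
write_var_model <- function(model, path) {
  stopifnot(inherits(model, "var_model"))
  m <- rbind(model$phi, model$noise_vars)
  colnames(m) <- paste0("V", seq_len(model$p))
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_var_model
#' @export
read_var_model <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = TRUE))
  p <- ncol(m)
  if (nrow(m) != p + 1) {
    abort(sprintf("Expected %d rows (phi plus noise variances) for p = %d.", p + 1, p),
          class = "varcross_invalid_model_file")
  }
  var_model(m[seq_len(p), , drop = FALSE], noise_vars = m[p + 1, ])
}

#' Read and write simulated series as CSV
#'
#' One row per time point, header `V1 ... Vp`.
#'
#' @param ts Tibble or matrix of observations.
#' @param path File path.
#' @export
write_series <- function(ts, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(as_series_matrix(ts))), path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
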