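#' A multilevel population of VAR(1) models
#'
#' Represents the distribution of person-specific VAR(1) transition matrices
#' implied by a mixed (multilevel) VAR model: each "person" deviates from a
#' population fixed-effects matrix by independent Gaussian random effects,
#' entry by entry, and carries log-normally distributed innovation
#' variances. Draws are rejection-sampled to stationarity, so the population
#' is the Gaussian law truncated to the stationary region.
#'
#' The defaults describe a 6-variable population typical of experience-
#' sampling data: moderate autoregressive effects (fixed diagonal 0.25,
#' random-effect SD 0.15) and small cross-lagged effects centred at zero
#' (random-effect SD 0.10). The off-diagonal spread is calibrated so the
#' sampled mean absolute cross-lagged effect O covers roughly 0.05-0.09,
#' the range spanned by typical person-specific models estimated from
#' experience-sampling data.
#'
#' @param fixed_phi `p x p` fixed-effects matrix; default diagonal 0.25.
#' @param re_sd `p x p` matrix of nonnegative per-entry random-effect SDs;
#'   default 0.15 on the diagonal, 0.10 off it. A scalar is recycled to all
#'   entries.
#' @param noise_var_law Length-2 numeric `c(log_mean, log_sd)` of the
#'   log-normal law for innovation variances; default `c(0, 0.3)`.
#' @param p Number of variables (default 6, minimum 2).
#' @return An object of class `mixed_var_population`.
#' @examples
#' pop <- mixed_var_population()
#' pop
#' @export
mixed_var_population <- function(fixed_phi = NULL, re_sd = NULL,
                                 noise_var_law = c(log_mean = 0, log_sd = 0.3),
                                 p = 6) {
  if (p < 2) abort("A population needs p >= 2 variables.", class = "varcross_invalid_population")
  if (is.null(fixed_phi)) fixed_phi <- diag(0.25, p)
  fixed_phi <- as.matrix(fixed_phi)
  check_phi_matrix(fixed_phi)
  if (nrow(fixed_phi) != p) abort("`fixed_phi` does not match `p`.", class = "varcross_invalid_population")
  if (!is_stationary(fixed_phi)) {
    abort("`fixed_phi` must itself be stationary.", class = "varcross_nonstationary")
  }
  if (is.null(re_sd)) {
    re_sd <- matrix(0.10, p, p)
    diag(re_sd) <- 0.15
  }
  if (length(re_sd) == 1) re_sd <- matrix(re_sd, p, p)
  re_sd <- as.matrix(re_sd)
  if (!identical(dim(re_sd), dim(fixed_phi)) || any(!is.finite(re_sd)) || any(re_sd < 0)) {
    abort("`re_sd` must be a p x p matrix of nonnegative finite SDs.",
          class = "varcross_invalid_population")
  }
  noise_var_law <- as.numeric(noise_var_law)
  if (length(noise_var_law) != 2 || !all(is.finite(noise_var_law)) || noise_var_law[2] < 0) {
    abort("`noise_var_law` must be c(log_mean, log_sd) with log_sd >= 0.",
          class = "varcross_invalid_population")
  }
  structure(
    list(fixed_phi = unname(fixed_phi), re_sd = unname(re_sd),
         noise_var_law = setNames(noise_var_law, c("log_mean", "log_sd")), p = p),
    class = "mixed_var_population"
  )
}

#' @export
print.mixed_var_population <- function(x, ...) {
  cat(sprintf("<mixed_var_population> p = %d\n", x$p))
  cat(sprintf("fixed-effects D = %.3f, O = %.3f; re_sd diag %.3f, off-diag %.3f\n",
              characteristics(x$fixed_phi)$D, characteristics(x$fixed_phi)$O,
              mean(diag(x$re_sd)), mean(x$re_sd[row(x$re_sd) != col(x$re_sd)])))
  cat(sprintf("innovation variances ~ lognormal(%.2f, %.2f)\n",
              x$noise_var_law[1], x$noise_var_law[2]))
  invisible(x)
}

#' Draw one stationary VAR model from a population
#'
#' Adds independent Gaussian random effects (SDs `re_sd`) to the
#' fixed-effects matrix and rejects non-stationary draws; innovation
#' variances are drawn from the population's log-normal law.
#'
#' @param pop A [mixed_var_population()].
#' @param seed Optional integer seed (deterministic draw).
#' @param max_rejects Maximum consecutive non-stationary rejections before
#'   giving up (default 10000).
#' @return A [var_model()].
#' @export
draw_model <- function(pop, seed = NULL, max_rejects = 10000) {
  stopifnot(inherits(pop, "mixed_var_population"))
  if (!is.null(seed)) set.seed(seed)
  p <- pop$p
  for (k in seq_len(max_rejects)) {
    phi <- pop$fixed_phi + matrix(rnorm(p * p), p, p) * pop$re_sd
    if (is_stationary(phi)) {
      nv <- rlnorm(p, pop$noise_var_law[1], pop$noise_var_law[2])
      return(var_model(phi, noise_vars = nv))
    }
  }
  abort(sprintf("Population infeasible: %d consecutive non-stationary draws.", max_rejects),
        class = "varcross_population_infeasible", rejects = max_rejects)
}

#' Build an equally spaced grid over the D-O plane
#'
#' Each axis is split into `k` equally spaced intervals spanning the
#' empirical min and max of the supplied characteristics. Intervals are
#' half-open `[lo, hi)` with the last interval closed, so every point maps
#' to exactly one cell. Only cells containing at least one input point are
#' retained. If an axis is constant it degenerates to a single interval and
#' is flagged.
#'
#' @param chars Data frame with numeric columns `D` and `O`, one row per
#'   model (e.g. stacked rows of [characteristics()]).
#' @param k Number of intervals per axis (default 15).
#' @return An object of class `do_grid`: `d_edges`, `o_edges` (length
#'   `k + 1`), `cells` (tibble of retained `d_bin`, `o_bin`, 1-based, with
#'   counts), `assignments` (tibble `idx`, `d_bin`, `o_bin`), and degeneracy
#'   flags.
#' @export
build_grid <- function(chars, k = 15) {
  chars <- tibble::as_tibble(chars)
  stopifnot(all(c("D", "O") %in% names(chars)), nrow(chars) >= 1, k >= 1)
  axis_edges <- function(x) {
    lo <- min(x); hi <- max(x)
    if (lo == hi) list(edges = c(lo, hi), degenerate = TRUE)
    else list(edges = seq(lo, hi, length.out = k + 1), degenerate = FALSE)
  }
  dax <- axis_edges(chars$D)
  oax <- axis_edges(chars$O)
  assignments <- tibble::tibble(
    idx = seq_len(nrow(chars)),
    d_bin = bin_index(chars$D, dax$edges),
    o_bin = bin_index(chars$O, oax$edges)
  )
  cells <- assignments |>
    dplyr::count(.data$d_bin, .data$o_bin, name = "n_pilot") |>
    dplyr::arrange(.data$d_bin, .data$o_bin)
  structure(
    list(d_edges = dax$edges, o_edges = oax$edges,
         k_d = length(dax$edges) - 1, k_o = length(oax$edges) - 1,
         cells = cells, assignments = assignments,
         degenerate_d = dax$degenerate, degenerate_o = oax$degenerate),
    class = "do_grid"
  )
}

# Half-open [lo, hi) bins, last bin closed; degenerate axes map to bin 1.
# Values outside the edge span belong to no bin and return NA.
bin_index <- function(x, edges) {
  if (length(edges) == 2 && edges[1] == edges[2]) {
    return(ifelse(x == edges[1], 1L, NA_integer_))
  }
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  as.integer(ifelse(i >= 1 & i <= length(edges) - 1, i, NA_integer_))
}

#' @export
print.do_grid <- function(x, ...) {
  cat(sprintf("<do_grid> %d x %d cells, %d retained (non-empty)\n",
              x$k_d, x$k_o, nrow(x$cells)))
  cat(sprintf("D in [%.3f, %.3f], O in [%.3f, %.3f]\n",
              min(x$d_edges), max(x$d_edges), min(x$o_edges), max(x$o_edges)))
  invisible(x)
}

grid_cell_of <- function(grid, D, O) {
  tibble::tibble(d_bin = bin_index(D, grid$d_edges),
                 o_bin = bin_index(O, grid$o_edges))
}

#' Stratified sampling of VAR models over the D-O grid
#'
#' Draws models from the population until every retained grid cell holds
#' exactly `per_cell` models; draws landing in full or non-retained cells
#' are discarded, which keeps cell sizes constant and results comparable
#' across cells. Deterministic in `seed`.
#'
#' @param pop A [mixed_var_population()].
#' @param grid A [build_grid()] result from a pilot sample of the same
#'   population.
#' @param per_cell Models per retained cell (default 100).
#' @param seed Integer seed for the draw stream.
#' @param budget Maximum number of draws before giving up; exhausting it
#'   raises a partial-fill error listing the underfilled cells.
#' @return A `model_collection`: a tibble with one row per model and columns
#'   `model_id` (integer), `D`, `O`, `d_bin`, `o_bin`, `seed` (the draw's own
#'   seed) and a list-column `model` of [var_model()] objects.
#' @export
stratified_fill <- function(pop, grid, per_cell = 100, seed = 1,
                            budget = 1000 * per_cell * nrow(grid$cells)) {
  stopifnot(inherits(pop, "mixed_var_population"), inherits(grid, "do_grid"),
            per_cell >= 1, budget >= 1)
  cells <- grid$cells
  key <- paste(cells$d_bin, cells$o_bin)
  counts <- setNames(integer(nrow(cells)), key)
  kept <- vector("list", per_cell * nrow(cells))
  kept_meta <- vector("list", per_cell * nrow(cells))
  n_kept <- 0
  for (attempt in seq_len(budget)) {
    s <- mix_seed(seed, attempt)
    m <- draw_model(pop, seed = s)
    ch <- characteristics(m)
    cell <- grid_cell_of(grid, ch$D, ch$O)
    if (is.na(cell$d_bin) || is.na(cell$o_bin)) next
    ck <- paste(cell$d_bin, cell$o_bin)
    if (!ck %in% key || counts[[ck]] >= per_cell) next
    counts[[ck]] <- counts[[ck]] + 1L
    n_kept <- n_kept + 1
    kept[[n_kept]] <- m
    kept_meta[[n_kept]] <- tibble::tibble(
      D = ch$D, O = ch$O, d_bin = cell$d_bin, o_bin = cell$o_bin, seed = s
    )
    if (n_kept == length(kept)) break
  }
  if (n_kept < length(kept)) {
    under <- cells |>
      dplyr::mutate(filled = unname(counts[key])) |>
      dplyr::filter(.data$filled < per_cell)
    abort(
      paste0("Draw budget exhausted before filling the grid; underfilled cells: ",
             paste(sprintf("(%d,%d): %d/%d", under$d_bin, under$o_bin,
                           under$filled, per_cell), collapse = ", ")),
      class = "varcross_partial_fill", underfilled = under
    )
  }
  out <- dplyr::bind_rows(kept_meta[seq_len(n_kept)]) |>
    dplyr::mutate(model_id = dplyr::row_number(), .before = 1)
  out$model <- kept[seq_len(n_kept)]
  class(out) <- c("model_collection", class(out))
  out
}

#' Population-probability weights for a model collection
#'
#' Reweights a model collection so that weighted summaries estimate
#' expectations over the population rather than over the stratified design.
#'
#' * `mode = "cell"` (the statistically matched choice for a
#'   [stratified_fill()] collection): each model is weighted by its grid
#'   cell's pilot frequency — the population probability of the cell —
#'   divided by the number of collection models in that cell. Within a cell
#'   the kept draws already follow the population law, so the cell
#'   probability is the exact importance weight for the stratification.
#'   Requires `grid` and `d_bin`/`o_bin` columns.
#' * `mode = "density"`: the product over matrix entries of the Gaussian
#'   density of \eqn{\Phi_{ij} - \mu_{ij}} with SD `re_sd[i,j]`. Entries
#'   with `re_sd = 0` contribute weight 0 if the model deviates there.
#'   Appropriate when the collection is not stratified.
#' * `mode = "uniform"`: every model gets weight `1/n` (robustness check).
#'
#' Weights are normalised to sum to 1 over the collection.
#'
#' @param collection A `model_collection` from [stratified_fill()], or any
#'   tibble with a `model` list-column.
#' @param pop The generating [mixed_var_population()].
#' @param mode `"cell"`, `"density"` or `"uniform"`.
#' @param grid The [build_grid()] result whose pilot counts define cell
#'   probabilities; required for `mode = "cell"`.
#' @return The collection with a `weight` column (sums to 1).
#' @export
model_weights <- function(collection, pop, mode = c("cell", "density", "uniform"),
                          grid = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pop, "mixed_var_population"), "model" %in% names(collection))
  n <- nrow(collection)
  if (mode == "uniform") {
    w <- rep(1 / n, n)
  } else if (mode == "cell") {
    if (is.null(grid) || !inherits(grid, "do_grid") ||
        !all(c("d_bin", "o_bin") %in% names(collection))) {
      abort('`mode = "cell"` needs the pilot `grid` and d_bin/o_bin columns.',
            class = "varcross_invalid_input")
    }
    joined <- dplyr::left_join(
      dplyr::select(tibble::as_tibble(collection), "d_bin", "o_bin") |>
        dplyr::mutate(.row = dplyr::row_number()) |>
        dplyr::add_count(.data$d_bin, .data$o_bin, name = ".in_cell"),
      grid$cells, by = c("d_bin", "o_bin")
    )
    if (any(is.na(joined$n_pilot))) {
      abort("Some models sit in cells unknown to the pilot grid.",
            class = "varcross_invalid_input")
    }
    w <- joined$n_pilot / joined$.in_cell
    w <- w / sum(w)
  } else {
    lw <- purrr::map_dbl(collection$model, function(m) {
      dev <- m$phi - pop$fixed_phi
      sdv <- pop$re_sd
      ok <- sdv > 0
      l <- sum(dnorm(dev[ok], sd = sdv[ok], log = TRUE))
      if (any(!ok & dev != 0)) l <- -Inf
      l
    })
    if (all(!is.finite(lw))) {
      abort("All models have zero density under this population.",
            class = "varcross_degenerate_weights")
    }
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(lw)] <- 0
    w <- w / sum(w)
  }
  dplyr::mutate(collection, weight = w)
}

#' Read and write population specifications as YAML
#'
#' @param pop A [mixed_var_population()].
#' @param path File path.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "mixed_var_population"))
  yaml::write_yaml(list(
    p = pop$p,
    fixed_phi = apply(pop$fixed_phi, 1, as.numeric, simplify = FALSE),
    re_sd = apply(pop$re_sd, 1, as.numeric, simplify = FALSE),
    noise_var_law = as.numeric(pop$noise_var_law)
  ), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  y <- yaml::read_yaml(path)
  mixed_var_population(
    fixed_phi = do.call(rbind, y$fixed_phi),
    re_sd = do.call(rbind, y$re_sd),
    noise_var_law = y$noise_var_law,
    p = y$p
  )
}
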