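test_that("degenerate populations behave as specified", {
  p <- 3
  fixed <- diag(0.4, p)
  pop0 <- mixed_var_population(fixed, re_sd = matrix(0, p, p), p = p)
  m <- draw_model(pop0, seed = 1)
  expect_identical(m$phi, fixed) # zero spread returns the fixed effects exactly

  # a never-stationary degenerate population is reported as infeasible
  pop_bad <- mixed_var_population(diag(0.99, p), re_sd = matrix(0, p, p), p = p)
  pop_bad$fixed_phi <- diag(p) # bypass constructor check to hit the sampler's guard
  expect_error(draw_model(pop_bad, seed = 1, max_rejects = 50),
               class = "varcross_population_infeasible")
})

test_that("every drawn model is stationary and deterministic in its seed", {
  pop <- mixed_var_population()
  ms <- lapply(1:50, function(i) draw_model(pop, seed = mix_seed(3, i)))
  expect_true(all(vapply(ms, function(m) is_stationary(m$phi), logical(1))))
  expect_true(all(vapply(ms, function(m) all(m$noise_vars > 0), logical(1))))
  again <- draw_model(pop, seed = mix_seed(3, 7))
  expect_identical(again$phi, ms[[7]]$phi)
  expect_identical(again$noise_vars, ms[[7]]$noise_vars)
})

test_that("default population spreads D and O over a realistic range", {
  pop <- mixed_var_population()
  ch <- dplyr::bind_rows(lapply(1:400, function(i) {
    characteristics(draw_model(pop, seed = mix_seed(9, i)))
  }))
  # brackets the reference models discussed in the vignette (D = 0.068 /
  # 0.337, O = 0.092 / 0.051): O must reach both sides of [0.05, 0.09]
  expect_lt(min(ch$D), 0.15)
  expect_gt(max(ch$D), 0.35)
  expect_lt(min(ch$O), 0.055)
  expect_gt(max(ch$O), 0.09)
})

test_that("grid binning uses half-open intervals with a closed last interval", {
  # all models at one point: a single retained cell on a degenerate grid
  one <- build_grid(tibble::tibble(D = rep(0.3, 5), O = rep(0.1, 5)), k = 15)
  expect_equal(nrow(one$cells), 1)
  expect_true(one$degenerate_d && one$degenerate_o)

  # two opposite corners retain exactly the two corner cells
  two <- build_grid(tibble::tibble(D = c(0, 1), O = c(0, 1)), k = 15)
  expect_equal(nrow(two$cells), 2)
  expect_equal(two$assignments$d_bin, c(1L, 15L))
  expect_equal(two$assignments$o_bin, c(1L, 15L))

  # hand binning: D in {0.1, 0.2, 0.3} with k = 2 splits at 0.2
  three <- build_grid(tibble::tibble(D = c(0.1, 0.2, 0.3), O = rep(0.05, 3)), k = 2)
  expect_equal(three$d_edges, c(0.1, 0.2, 0.3))
  expect_equal(three$assignments$d_bin, c(1L, 2L, 2L))
  expect_true(three$degenerate_o)
})

test_that("grid assignment is a partition", {
  pop <- mixed_var_population()
  ch <- dplyr::bind_rows(lapply(1:200, function(i) {
    characteristics(draw_model(pop, seed = mix_seed(31, i)))
  }))
  grid <- build_grid(ch, k = 10)
  expect_equal(nrow(grid$assignments), 200)
  expect_false(any(is.na(grid$assignments$d_bin)))
  expect_true(all(grid$assignments$d_bin %in% 1:10))
  expect_true(all(grid$assignments$o_bin %in% 1:10))
  # every retained cell's pilot count matches its members
  counts <- dplyr::count(grid$assignments, d_bin, o_bin)
  expect_equal(sum(counts$n), 200)
  expect_equal(nrow(counts), nrow(grid$cells))
})

test_that("stratified filling yields exactly per_cell models per retained cell", {
  pop <- mixed_var_population(p = 3)
  pilot <- dplyr::bind_rows(lapply(1:80, function(i) {
    characteristics(draw_model(pop, seed = mix_seed(41, i)))
  }))
  grid <- build_grid(pilot, k = 3)
  coll <- stratified_fill(pop, grid, per_cell = 5, seed = 42, budget = 100000)
  expect_s3_class(coll, "model_collection")
  expect_equal(nrow(coll), 5 * nrow(grid$cells))
  counts <- dplyr::count(coll, d_bin, o_bin)
  expect_true(all(counts$n == 5))
  # each model's characteristics lie inside its assigned cell
  recomputed <- dplyr::bind_rows(lapply(coll$model, characteristics))
  expect_equal(coll$D, recomputed$D)
  expect_true(all(vapply(seq_len(nrow(coll)), function(i) {
    d <- coll$D[i]
    lo <- grid$d_edges[coll$d_bin[i]]; hi <- grid$d_edges[coll$d_bin[i] + 1]
    d >= lo && (d < hi || (coll$d_bin[i] == length(grid$d_edges) - 1 && d <= hi))
  }, logical(1))))
  expect_true(all(vapply(coll$model, function(m) is_stationary(m$phi), logical(1))))

  # identical seeds reproduce the collection exactly
  coll2 <- stratified_fill(pop, grid, per_cell = 5, seed = 42, budget = 100000)
  expect_identical(coll$seed, coll2$seed)
  expect_identical(coll$model[[3]]$phi, coll2$model[[3]]$phi)
})

test_that("an unreachable cell triggers a partial-fill error naming it", {
  pop <- mixed_var_population(p = 3)
  pilot <- dplyr::bind_rows(lapply(1:40, function(i) {
    characteristics(draw_model(pop, seed = mix_seed(51, i)))
  }))
  grid <- build_grid(pilot, k = 2)
  # a fluke cell far outside the population's reach
  grid$cells <- dplyr::bind_rows(grid$cells,
                                 tibble::tibble(d_bin = 2L, o_bin = 2L, n_pilot = 1L))
  grid$cells <- dplyr::distinct(grid$cells, d_bin, o_bin, .keep_all = TRUE)
  grid$d_edges <- c(0, 0.2, 10) # push bin 2 to D in [0.2, 10]: reachable
  grid$o_edges <- c(0, 5, 10)   # but O in [5, 10] is impossible for stationary models
  err <- tryCatch(
    stratified_fill(pop, grid, per_cell = 1, seed = 1, budget = 300),
    error = function(e) e
  )
  expect_s3_class(err, "varcross_partial_fill")
  expect_true(any(err$underfilled$o_bin == 2))
})

test_that("population weights normalise, peak at the fixed effects, and support uniform mode", {
  pop <- mixed_var_population(p = 3)
  pilot <- dplyr::bind_rows(lapply(1:60, function(i) {
    characteristics(draw_model(pop, seed = mix_seed(61, i)))
  }))
  grid <- build_grid(pilot, k = 2)
  coll <- stratified_fill(pop, grid, per_cell = 3, seed = 7, budget = 100000)
  # append the fixed-effects matrix itself: it must get the largest weight
  centre <- tibble::tibble(model_id = max(coll$model_id) + 1L,
                           D = characteristics(pop$fixed_phi)$D,
                           O = characteristics(pop$fixed_phi)$O,
                           d_bin = NA_integer_, o_bin = NA_integer_, seed = NA_integer_)
  centre$model <- list(var_model(pop$fixed_phi))
  coll_c <- dplyr::bind_rows(coll, centre)
  wd <- model_weights(coll_c, pop, mode = "density")
  expect_equal(sum(wd$weight), 1, tolerance = 1e-12)
  expect_equal(which.max(wd$weight), nrow(wd))
  wu <- model_weights(coll_c, pop, mode = "uniform")
  expect_true(all(wu$weight == 1 / nrow(wu)))

  # zero-sd entries give zero weight to deviating models, not an error
  pop0 <- mixed_var_population(p = 3)
  pop0$re_sd[1, 2] <- 0
  at_centre <- pop0$fixed_phi # zero deviation everywhere: positive weight
  deviating <- pop0$fixed_phi
  deviating[1, 2] <- 0.05 # deviates exactly where the random effect is pinned
  pair <- tibble::tibble(model_id = 1:2)
  pair$model <- list(var_model(deviating), var_model(at_centre))
  w0 <- model_weights(pair, pop0, mode = "density")
  expect_equal(w0$weight, c(0, 1))
})

test_that("population YAML round-trips", {
  pop <- mixed_var_population(p = 4)
  path <- tempfile(fileext = ".yaml")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$fixed_phi, pop$fixed_phi)
  expect_equal(back$re_sd, pop$re_sd)
  expect_equal(unname(back$noise_var_law), unname(pop$noise_var_law))
  expect_equal(back$p, 4)
})

test_that("cell weights undo the stratification using pilot frequencies", {
  pop <- mixed_var_population(p = 3)
  pilot <- dplyr::bind_rows(lapply(1:200, function(i) {
    characteristics(draw_model(pop, seed = mix_seed(71, i)))
  }))
  grid <- build_grid(pilot, k = 2)
  coll <- stratified_fill(pop, grid, per_cell = 2, seed = 3, budget = 100000)
  w <- model_weights(coll, pop, mode = "cell", grid = grid)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  # each model carries its cell's pilot probability split over the 2 models
  joined <- dplyr::left_join(tibble::as_tibble(w), grid$cells,
                             by = c("d_bin", "o_bin"))
  expect_equal(w$weight, joined$n_pilot / 2 / sum(grid$cells$n_pilot))
  # cell mode requires the grid
  expect_error(model_weights(coll, pop, mode = "cell"),
               class = "varcross_invalid_input")
})
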