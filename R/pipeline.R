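#' Pipeline configurations
#'
#' A configuration is a plain nested list (serialisable as YAML) with four
#' blocks: `population` (the multilevel population of true models),
#' `sampling` (how models are drawn and stratified on the D-O grid),
#' `experiment` (the Monte-Carlo error-curve design) and `selection`
#' (rule-comparison settings), plus a `master_seed`.
#'
#' `default_config()` is a scaled-down version of the full study, sized to
#' run on a single CPU in minutes: about 150 models (stratified, one per
#' retained cell of a 15 x 15 grid built from a 1000-draw pilot), an n-grid
#' of 8, 10, ..., 200 and 20 replicates. `full_scale_config()` carries the
#' full design (100 models per cell from a 10000-draw pilot, n-grid
#' 8, 9, ..., 500, 100 replicates); it needs cluster-style patience.
#' `smoke_config()` is a seconds-scale end-to-end check (p = 3, 4 models
#' drawn without stratification, three n values, 3 replicates).
#'
#' @param master_seed Integer master seed (default 1).
#' @return A named list.
#' @export
default_config <- function(master_seed = 1) {
  list(
    population = list(p = 6, fixed_phi_diag = 0.25, fixed_phi_offdiag = 0,
                      re_sd_diag = 0.15, re_sd_offdiag = 0.10,
                      noise_log_mean = 0, noise_log_sd = 0.3),
    sampling = list(mode = "grid", pilot_n = 1000, k = 15, per_cell = 1,
                    budget = 500000, weight_mode = "cell"),
    experiment = list(n_min = 8, n_max = 200, n_step = 2,
                      reps = 20, n_test = 2000, burn_in = 100),
    selection = list(se_reference = "var"),
    master_seed = as.integer(master_seed)
  )
}

#' @rdname default_config
#' @export
full_scale_config <- function(master_seed = 1) {
  cfg <- default_config(master_seed)
  cfg$sampling$pilot_n <- 10000
  cfg$sampling$per_cell <- 100
  cfg$sampling$budget <- 5e7
  cfg$experiment <- list(n_min = 8, n_max = 500, n_step = 1,
                         reps = 100, n_test = 2000, burn_in = 100)
  cfg
}

#' @rdname default_config
#' @export
smoke_config <- function(master_seed = 1) {
  list(
    population = list(p = 3, fixed_phi_diag = 0.25, fixed_phi_offdiag = 0,
                      re_sd_diag = 0.15, re_sd_offdiag = 0.10,
                      noise_log_mean = 0, noise_log_sd = 0.3),
    sampling = list(mode = "simple", n_models = 4, weight_mode = "density"),
    experiment = list(n_grid = c(10, 20, 40), reps = 3, n_test = 200, burn_in = 50),
    selection = list(se_reference = "var"),
    master_seed = as.integer(master_seed)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing blocks and fields fall back to [default_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Schema errors name the offending key.
#'
#' @param cfg Configuration list.
#' @return The configuration, invisibly usable, or an error.
#' @export
validate_config <- function(cfg) {
  fail <- function(key, msg) {
    abort(sprintf("Invalid config key `%s`: %s", key, msg),
          class = "varcross_invalid_config")
  }
  pb <- cfg$population
  if (is.null(pb$p) || pb$p < 2) fail("population.p", "need p >= 2")
  sb <- cfg$sampling
  mode <- sb$mode %||% "grid"
  if (!mode %in% c("grid", "simple")) fail("sampling.mode", 'must be "grid" or "simple"')
  if (mode == "grid") {
    if ((sb$pilot_n %||% 0) < 2) fail("sampling.pilot_n", "need >= 2 pilot draws")
    if ((sb$per_cell %||% 0) < 1) fail("sampling.per_cell", "need >= 1 model per cell")
  } else if ((sb$n_models %||% 0) < 1) fail("sampling.n_models", "need >= 1 model")
  eb <- cfg$experiment
  if (is.null(eb$reps) || eb$reps < 2) {
    fail("reps", "need >= 2 replicates (replicate SDs are undefined otherwise)")
  }
  grid <- config_n_grid(cfg)
  if (length(grid) < 1 || min(grid) < 3 || is.unsorted(grid, strictly = TRUE)) {
    fail("experiment.n_grid", "must be strictly ascending with minimum >= 3")
  }
  if ((eb$n_test %||% 0) < 2) fail("experiment.n_test", "need n_test >= 2")
  if (is.null(cfg$master_seed) || !is.finite(cfg$master_seed)) {
    fail("master_seed", "must be a finite integer")
  }
  cfg
}

config_n_grid <- function(cfg) {
  eb <- cfg$experiment
  if (!is.null(eb$n_grid)) as.integer(eb$n_grid)
  else as.integer(seq(eb$n_min, eb$n_max, by = eb$n_step %||% 1))
}

config_population <- function(cfg) {
  pb <- cfg$population
  p <- pb$p
  fixed_phi <- if (!is.null(pb$fixed_phi)) {
    do.call(rbind, pb$fixed_phi)
  } else {
    m <- matrix(pb$fixed_phi_offdiag %||% 0, p, p)
    diag(m) <- pb$fixed_phi_diag %||% 0.25
    m
  }
  re_sd <- if (!is.null(pb$re_sd)) {
    do.call(rbind, pb$re_sd)
  } else {
    m <- matrix(pb$re_sd_offdiag %||% 0.10, p, p)
    diag(m) <- pb$re_sd_diag %||% 0.15
    m
  }
  mixed_var_population(fixed_phi, re_sd,
                       noise_var_law = c(pb$noise_log_mean %||% 0,
                                         pb$noise_log_sd %||% 0.3),
                       p = p)
}

config_experiment <- function(cfg) {
  eb <- cfg$experiment
  experiment_config(n_grid = config_n_grid(cfg), reps = eb$reps,
                    n_test = eb$n_test %||% 2000, burn_in = eb$burn_in %||% 100,
                    master_seed = cfg$master_seed)
}

#' Sample the model collection of a configured study
#'
#' Runs the model-sampling stage in memory: pilot draws, D-O grid
#' construction, stratified filling and population weights (or simple
#' random draws when `sampling.mode = "simple"`).
#'
#' @param cfg Validated configuration list.
#' @return A weighted `model_collection`.
#' @export
sample_models <- function(cfg) {
  pop <- config_population(cfg)
  sb <- cfg$sampling
  if ((sb$mode %||% "grid") == "grid") {
    pilot <- purrr::map(seq_len(sb$pilot_n), function(i) {
      draw_model(pop, seed = mix_seed(cfg$master_seed, 101, i))
    })
    chars <- dplyr::bind_rows(purrr::map(pilot, characteristics))
    grid <- build_grid(chars, k = sb$k %||% 15)
    coll <- stratified_fill(pop, grid, per_cell = sb$per_cell,
                            seed = mix_seed(cfg$master_seed, 202),
                            budget = sb$budget %||% (1000 * sb$per_cell * nrow(grid$cells)))
    return(model_weights(coll, pop, mode = sb$weight_mode %||% "cell", grid = grid))
  } else {
    models <- purrr::map(seq_len(sb$n_models), function(i) {
      draw_model(pop, seed = mix_seed(cfg$master_seed, 303, i))
    })
    coll <- dplyr::bind_rows(purrr::map(models, characteristics)) |>
      dplyr::mutate(model_id = dplyr::row_number(), .before = 1) |>
      dplyr::mutate(d_bin = NA_integer_, o_bin = NA_integer_,
                    seed = purrr::map_int(.data$model_id,
                                          ~ mix_seed(cfg$master_seed, 303, .x)))
    coll$model <- models
    class(coll) <- c("model_collection", class(coll))
  }
  model_weights(coll, pop, mode = sb$weight_mode %||% "density")
}

write_models <- function(coll, out_dir) {
  p <- coll$model[[1]]$p
  phi_long <- purrr::map2(coll$model, coll$model_id, function(m, id) {
    tibble::tibble(model_id = id,
                   row = rep(seq_len(p), times = p),
                   col = rep(seq_len(p), each = p),
                   value = as.numeric(m$phi))
  }) |> dplyr::bind_rows()
  noise_long <- purrr::map2(coll$model, coll$model_id, function(m, id) {
    tibble::tibble(model_id = id, variable = seq_len(p), value = m$noise_vars)
  }) |> dplyr::bind_rows()
  manifest <- dplyr::select(tibble::as_tibble(coll), -"model")
  readr::write_csv(phi_long, file.path(out_dir, "models_phi.csv"))
  readr::write_csv(noise_long, file.path(out_dir, "models_noise.csv"))
  readr::write_csv(manifest, file.path(out_dir, "models_manifest.csv"))
  invisible(coll)
}

read_models <- function(out_dir) {
  need <- file.path(out_dir, c("models_phi.csv", "models_noise.csv", "models_manifest.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste0("Missing upstream outputs: ", paste(basename(missing), collapse = ", "),
                 ". Run the sample-models stage first."),
          class = "varcross_missing_stage")
  }
  phi_long <- readr::read_csv(need[1], show_col_types = FALSE)
  noise_long <- readr::read_csv(need[2], show_col_types = FALSE)
  manifest <- readr::read_csv(need[3], show_col_types = FALSE)
  models <- purrr::map(manifest$model_id, function(id) {
    ph <- dplyr::filter(phi_long, .data$model_id == id)
    p <- max(ph$row)
    phi <- matrix(0, p, p)
    phi[cbind(ph$row, ph$col)] <- ph$value
    nv <- dplyr::filter(noise_long, .data$model_id == id)$value
    var_model(phi, noise_vars = nv)
  })
  manifest$model <- models
  class(manifest) <- c("model_collection", class(manifest))
  manifest
}

#' Run the simulation pipeline end to end
#'
#' Executes the study stages in order — `sample-models` (population draws,
#' D-O grid, weights), `run-curves` (Monte-Carlo error curves),
#' `crossings` (n_e / n_p / n_gap summaries), `compare-rules` (minimum
#' prediction error vs the one-standard-error rule) and `report` (run
#' manifest) — writing long-format CSV and JSON outputs to `out_dir`. A
#' single stage can be re-run from the prior stages' files with `stage`.
#' Outputs are a pure function of (configuration, master seed): rerunning
#' with the same inputs reproduces them byte for byte (the run manifest
#' additionally carries wall-clock timestamps).
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param out_dir Output directory, created if needed.
#' @param stage `"all"` (default) or one of `"sample-models"`,
#'   `"run-curves"`, `"crossings"`, `"compare-rules"`, `"report"`.
#' @param progress Print progress messages? Default `FALSE`.
#' @return The run manifest, invisibly: configuration snapshot, seed,
#'   package version, per-file row counts and timestamps.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stage = c("all", "sample-models", "run-curves",
                                   "crossings", "compare-rules", "report"),
                         progress = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  stages <- if (stage == "all") {
    c("sample-models", "run-curves", "crossings", "compare-rules", "report")
  } else stage

  if ("sample-models" %in% stages) {
    coll <- sample_models(cfg)
    write_models(coll, out_dir)
    if (progress) message("sampled ", nrow(coll), " models")
  }
  if ("run-curves" %in% stages) {
    coll <- read_models(out_dir)
    curves <- run_collection(coll, config_experiment(cfg), progress = progress)
    readr::write_csv(curves, file.path(out_dir, "curves.csv"))
  }
  if ("crossings" %in% stages) {
    curves <- read_curves(out_dir)
    manifest <- readr::read_csv(file.path(out_dir, "models_manifest.csv"),
                                show_col_types = FALSE)
    summaries <- crossing_summary(curves) |>
      dplyr::left_join(dplyr::select(manifest, "model_id", "D", "O", "weight"),
                       by = "model_id")
    readr::write_csv(summaries, file.path(out_dir, "crossings.csv"))
    report <- tryCatch(
      unclass_report(summarize_collection(summaries, weights = manifest,
                                          gap_binwidth = cfg$selection$gap_binwidth)),
      varcross_empty_summary = function(e) list(
        n_e = NULL, n_gap = NULL, correlations = NULL,
        censoring = list(n_models = nrow(summaries),
                         n_e_censored = sum(summaries$n_e_censored),
                         n_p_censored = sum(summaries$n_p_censored),
                         n_gap_censored = sum(summaries$n_gap_censored)),
        note = "all crossings censored on this n-grid"
      )
    )
    write_report_json(report, file.path(out_dir, "crossing_report.json"))
  }
  if ("compare-rules" %in% stages) {
    curves <- read_curves(out_dir)
    manifest <- readr::read_csv(file.path(out_dir, "models_manifest.csv"),
                                show_col_types = FALSE)
    rules <- compare_rules(curves, weights = manifest,
                           se_reference = cfg$selection$se_reference %||% "var")
    readr::write_csv(rules$outcomes, file.path(out_dir, "selection_outcomes.csv"))
    readr::write_csv(rules$ee_comp_curve, file.path(out_dir, "ee_comp_curve.csv"))
    write_report_json(list(disagreement = as.list(rules$disagreement),
                           se_reference = rules$se_reference),
                      file.path(out_dir, "rules_report.json"))
  }
  manifest <- NULL
  if ("report" %in% stages || stage == "all") {
    files <- c("models_phi.csv", "models_noise.csv", "models_manifest.csv",
               "curves.csv", "crossings.csv", "crossing_report.json",
               "selection_outcomes.csv", "ee_comp_curve.csv", "rules_report.json")
    files <- files[file.exists(file.path(out_dir, files))]
    rows <- vapply(files, function(f) {
      path <- file.path(out_dir, f)
      if (grepl("[.]csv$", f)) nrow(readr::read_csv(path, show_col_types = FALSE))
      else NA_integer_
    }, integer(1))
    manifest <- list(
      package_version = as.character(packageVersion("varcross")),
      master_seed = cfg$master_seed,
      config = cfg,
      outputs = purrr::map2(files, rows, function(f, r) {
        list(file = f, rows = if (is.na(r)) NULL else r)
      }),
      started = started,
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    write_report_json(manifest, file.path(out_dir, "run_manifest.json"))
  }
  invisible(manifest)
}

read_curves <- function(out_dir) {
  path <- file.path(out_dir, "curves.csv")
  if (!file.exists(path)) {
    abort("Missing upstream output curves.csv. Run the run-curves stage first.",
          class = "varcross_missing_stage")
  }
  curves <- readr::read_csv(path, show_col_types = FALSE)
  class(curves) <- c("error_curves", class(curves))
  curves
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

unclass_report <- function(report) {
  list(
    n_e = as.list(report$n_e),
    n_gap = if (!is.null(report$n_gap)) {
      list(mean = report$n_gap$mean, skewness = report$n_gap$skewness,
           mode_bin = as.list(report$n_gap$mode_bin),
           histogram = report$n_gap$histogram)
    },
    correlations = report$correlations,
    censoring = as.list(report$censoring)
  )
}
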