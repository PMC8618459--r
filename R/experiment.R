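#' Full experiment configuration
#'
#' One hierarchical configuration object covering every switch of the
#' pipeline, with the best-performing setting of each as the default:
#' full-horizon data range, averaged LACE/HOSPITAL initial probability,
#' exponential daily function with reset-to-initial readmitted handling,
#' 2-day moving-average imputation, first-day feature filtering on, all
#' three feature sources, date index on, predicted-previous-probability
#' injection. Round-trips losslessly through JSON.
#'
#' @param trajectory A [trajectory_config()].
#' @param model An [lstm_config()].
#' @param features Named list of [preprocess_panel()] arguments
#'   (`deviation_window`, `max_missing_frac`, `min_variance`,
#'   `drop_if_first_day_missing`, `data_range`, `impute_k`,
#'   `fill_constant`, `sources`).
#' @param evaluation Named list with submetric windows `k`, `K`.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trajectory = trajectory_config(),
                       model = lstm_config(),
                       features = list(deviation_window = 7L,
                                       max_missing_frac = 0.8,
                                       min_variance = 0.3,
                                       drop_if_first_day_missing = TRUE,
                                       data_range = "full_60",
                                       impute_k = 2L, fill_constant = -1,
                                       sources = c("sensor", "symptom",
                                                   "deviation")),
                       evaluation = list(k = 20L, K = 60L),
                       seed = 1L) {
  structure(list(trajectory = trajectory, model = model, features = features,
                 evaluation = evaluation, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  out <- list(trajectory = unclass(config$trajectory),
              model = unclass(config$model),
              features = config$features,
              evaluation = config$evaluation,
              seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- raw$trajectory
  mo <- raw$model
  run_config(
    trajectory = trajectory_config(fun = tr$fun,
                                   initial_source = tr$initial_source,
                                   readmitted_mode = tr$readmitted_mode,
                                   horizon = tr$horizon),
    model = lstm_config(n_layers = mo$n_layers,
                        hidden_units = mo$hidden_units,
                        learning_rate = mo$learning_rate,
                        max_epochs = mo$max_epochs, patience = mo$patience,
                        injection = mo$injection,
                        include_date_index = mo$include_date_index,
                        seed = mo$seed),
    features = raw$features, evaluation = raw$evaluation, seed = raw$seed)
}

apply_overrides <- function(config, overrides) {
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      config[[parts]] <- overrides[[nm]]
    } else {
      config[[parts[1]]][[parts[2]]] <- overrides[[nm]]
    }
  }
  config
}

run_one_cell <- function(config, metas, panel_raw, name) {
  trajectories <- build_trajectories(metas, config$trajectory)
  f <- config$features
  panel <- preprocess_panel(panel_raw, metas,
                            deviation_window = f$deviation_window,
                            max_missing_frac = f$max_missing_frac,
                            min_variance = f$min_variance,
                            drop_if_first_day_missing = f$drop_if_first_day_missing,
                            data_range = f$data_range,
                            impute_k = f$impute_k,
                            fill_constant = f$fill_constant,
                            sources = f$sources)
  fit <- train_lopo(panel, trajectories, config$model)
  report <- submetrics(fit$predictions, metas, k = config$evaluation$k,
                       K = config$evaluation$K, model_name = name)
  list(fit = fit, report = report)
}

#' Train and rank a grid of experiment settings
#'
#' Runs the full pipeline (labels, preprocessing, leave-one-patient-out
#' LSTM, submetrics) once per grid cell and ranks the resulting models with
#' the composite point system. Each cell is the base configuration plus a
#' named list of overrides, addressed as `"section.field"` (e.g.
#' `list(model.injection = "actual_prev")`). A failed cell is logged and
#' excluded from the ranking.
#'
#' @param config Base [run_config()].
#' @param metas Named list of [patient_meta()].
#' @param panel Raw [feature_panel()].
#' @param grid Named list of override lists; names label the grid cells. An
#'   empty grid runs the base configuration only (no ranking).
#' @param out_dir Optional directory for per-cell prediction CSVs and the
#'   ranking table.
#' @return List with `reports`, `fits`, `ranking` (NULL for < 2 cells) and
#'   `failed`.
#' @export
run_experiment_grid <- function(config, metas, panel, grid = list(),
                                out_dir = NULL) {
  if (!length(grid)) grid <- list(base = list())
  if (is.null(names(grid))) names(grid) <- sprintf("cell%02d", seq_along(grid))
  reports <- list(); fits <- list(); failed <- character(0)
  for (nm in names(grid)) {
    cell <- tryCatch(
      run_one_cell(apply_overrides(config, grid[[nm]]), metas, panel, nm),
      error = function(e) {
        message("grid cell '", nm, "' failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(cell)) {
      failed <- c(failed, nm)
      next
    }
    reports[[nm]] <- cell$report
    fits[[nm]] <- cell$fit
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_predictions(cell$fit,
                        file.path(out_dir, paste0("predictions_", nm, ".csv")))
    }
  }
  ranking <- if (length(reports) >= 2) rank_models(reports) else NULL
  if (!is.null(ranking) && !is.null(out_dir)) {
    utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
  }
  list(reports = reports, fits = fits, ranking = ranking, failed = failed)
}
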