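#' Append deviation features
#'
#' For every base feature, adds the difference between the value on a day
#' and the mean of that feature over the preceding `window` days (observed
#' values only, current day excluded). Where no prior observed value exists
#' the deviation is missing. Appended columns are named `<feature>_dev<w>`
#' and tagged `deviation`.
#'
#' @param panel A [feature_panel()] (raw, pre-imputation).
#' @param window Number of strictly prior days in the averaging window.
#' @return The panel with deviation columns appended.
#' @export
deviation_features <- function(panel, window = 7L) {
  stopifnot(inherits(panel, "feature_panel"), window >= 1)
  base <- which(panel$tags %in% c("sensor", "symptom"))
  if (!length(base)) return(panel)
  d <- dim(panel$values)
  dev <- array(NA_real_, dim = c(d[1], d[2], length(base)))
  for (bi in seq_along(base)) {
    j <- base[bi]
    for (i in seq_len(d[1])) {
      x <- panel$values[i, , j]
      for (t in seq_len(panel$lengths[i])) {
        lo <- max(1L, t - window)
        if (lo > t - 1L) next
        prior <- x[lo:(t - 1L)]
        prior <- prior[!is.na(prior)]
        if (length(prior) && !is.na(x[t])) {
          dev[i, t, bi] <- x[t] - mean(prior)
        }
      }
    }
  }
  vals <- array(c(panel$values, dev), dim = c(d[1], d[2], d[3] + length(base)))
  feature_panel(vals, patients = panel$patients,
                features = c(panel$features,
                             sprintf("%s_dev%d", panel$features[base], window)),
                tags = c(panel$tags, rep("deviation", length(base))),
                lengths = panel$lengths)
}

#' Filter unusable feature columns
#'
#' Drops features that (pooled over all patients' active days) are missing
#' in more than `max_missing_frac` of cells, have variance of the observed
#' raw values below `min_variance`, or — when `drop_if_first_day_missing` —
#' are missing on day 1 for at least one patient (the first day initializes
#' the recurrent model; a feature absent there behaves as noise).
#'
#' @param panel A [feature_panel()].
#' @param max_missing_frac Missingness threshold (strictly-greater drops).
#' @param min_variance Minimum variance of observed values (strictly-less
#'   drops).
#' @param drop_if_first_day_missing Apply the day-1 rule?
#' @return Filtered panel; the drop log (feature, reason) is stored in
#'   `$log` and also attached to the manifest by [write_feature_manifest()].
#' @export
filter_features <- function(panel, max_missing_frac = 0.8, min_variance = 0.3,
                            drop_if_first_day_missing = TRUE) {
  stopifnot(inherits(panel, "feature_panel"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  act <- active_days(panel)
  d <- dim(panel$values)
  reasons <- character(0); dropped <- character(0)
  keep <- logical(d[3])
  for (j in seq_len(d[3])) {
    x <- panel$values[, , j][act]
    obs <- x[!is.na(x)]
    reason <- NULL
    if (mean(is.na(x)) > max_missing_frac) {
      reason <- sprintf("missing fraction %.2f > %.2f", mean(is.na(x)),
                        max_missing_frac)
    } else if (length(obs) < 2 || stats::var(obs) < min_variance) {
      reason <- sprintf("variance %.3f < %.2f",
                        if (length(obs) < 2) 0 else stats::var(obs),
                        min_variance)
    } else if (drop_if_first_day_missing && panel$tags[j] != "deviation" &&
               anyNA(panel$values[, 1, j])) {
      # deviation columns are exempt: with panels that start at discharge
      # their day-1 value is structurally missing (empty prior window), not
      # a data-quality signal
      reason <- "missing on day 1 for at least one patient"
    }
    if (is.null(reason)) {
      keep[j] <- TRUE
    } else {
      dropped <- c(dropped, panel$features[j])
      reasons <- c(reasons, reason)
    }
  }
  if (!any(keep)) {
    stop("all feature columns were dropped by the filters", call. = FALSE)
  }
  out <- feature_panel(panel$values[, , keep, drop = FALSE],
                       patients = panel$patients,
                       features = panel$features[keep],
                       tags = panel$tags[keep], lengths = panel$lengths)
  out$log <- if (length(dropped)) {
    data.frame(feature = dropped, reason = reasons)
  } else {
    data.frame(feature = character(0), reason = character(0))
  }
  out
}

#' Moving-average imputation with constant fallback
#'
#' Per patient and feature, each missing cell is replaced by the mean of up
#' to `k_prev` previous *observed* values of that patient/feature; cells
#' with no observed predecessor (e.g. a missing day 1) are set to
#' `fill_constant`, a value deliberately outside the data range so the model
#' can tell "imputed by constant" from real measurements.
#'
#' @param panel A [feature_panel()].
#' @param k_prev Number of previous observed days to average; `0` skips
#'   straight to the constant fill.
#' @param fill_constant Fallback value (default -1).
#' @return Panel with no missing cells; `$imputed` marks moving-average
#'   cells and `$filled` marks constant-filled cells.
#' @export
impute_moving_average <- function(panel, k_prev = 2L, fill_constant = -1) {
  stopifnot(inherits(panel, "feature_panel"), k_prev >= 0)
  d <- dim(panel$values)
  vals <- panel$values
  imput <- array(FALSE, dim = d)
  filled <- array(FALSE, dim = d)
  act <- active_days(panel)
  for (j in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      x <- panel$values[i, , j]
      for (t in seq_len(panel$lengths[i])) {
        if (!is.na(x[t])) next
        prev <- if (t > 1L && k_prev > 0L) {
          obs <- which(!is.na(x[seq_len(t - 1L)]))
          utils::tail(obs, k_prev)
        } else integer(0)
        if (length(prev)) {
          vals[i, t, j] <- mean(x[prev])
          imput[i, t, j] <- TRUE
        } else {
          vals[i, t, j] <- fill_constant
          filled[i, t, j] <- TRUE
        }
      }
    }
  }
  # inactive cells (past a patient's length) are zero-filled so downstream
  # matrix code never sees NA; they are masked out of every computation
  vals[is.na(vals)] <- fill_constant
  panel$values <- vals
  panel$imputed <- imput
  panel$filled <- filled
  panel$fill_constant <- fill_constant
  panel
}

#' Min-max normalization pooled over all patients
#'
#' Scales every feature to \[0, 1\] using its minimum and maximum over all
#' patients and days, the protocol required by the sigmoid/tanh recurrent
#' model. Constant-filled cells (the `fill_constant` of
#' [impute_moving_average()]) are excluded from the fit and left at the
#' constant, so they stay distinguishable from real values. Constant
#' features map to 0.
#'
#' @param panel An imputed [feature_panel()].
#' @param params Optional previously fitted scaling (list of `min`/`max`
#'   vectors) to apply instead of fitting, e.g. to avoid leaking the
#'   held-out patient into the fit.
#' @return Normalized panel with `$norm` holding `min`/`max` per feature.
#' @export
normalize_minmax <- function(panel, params = NULL) {
  stopifnot(inherits(panel, "feature_panel"))
  if (anyNA(panel$values)) {
    stop("panel still has missing cells; impute before normalizing", call. = FALSE)
  }
  d <- dim(panel$values)
  act <- active_days(panel)
  fitted <- is.null(params)
  if (fitted) {
    params <- list(min = numeric(d[3]), max = numeric(d[3]))
  }
  for (j in seq_len(d[3])) {
    x <- panel$values[, , j]
    use <- act
    if (!is.null(panel$filled)) use <- use & !panel$filled[, , j]
    if (fitted) {
      xs <- x[use]
      params$min[j] <- if (length(xs)) min(xs) else 0
      params$max[j] <- if (length(xs)) max(xs) else 0
    }
    rng <- params$max[j] - params$min[j]
    scaled <- if (rng > 0) (x - params$min[j]) / rng else x * 0
    scaled[!use] <- x[!use]   # keep fill constant / inactive cells as-is
    panel$values[, , j] <- scaled
  }
  names(params$min) <- names(params$max) <- panel$features
  panel$norm <- params
  panel
}

#' Attach auxiliary model inputs (date index, previous-day probability)
#'
#' Optionally appends (i) a normalized day-index column (day / horizon) and
#' (ii) the previous day's risk probability: on day t the column holds
#' p_{t-1}; on day 1 it holds the initial (day-1) probability, which is
#' known at discharge from the administrative scores.
#'
#' @param panel A [feature_panel()].
#' @param date_index Append the day-index column?
#' @param probabilities Optional named list (by patient) of per-day
#'   probability vectors, or a list of `risk_trajectory` objects.
#' @return Panel with columns `date_index` and/or `prev_probability`.
#' @export
attach_auxiliary <- function(panel, date_index = FALSE, probabilities = NULL) {
  stopifnot(inherits(panel, "feature_panel"))
  d <- dim(panel$values)
  add <- list(); tags <- character(0)
  if (date_index) {
    col <- matrix(rep(seq_len(d[2]) / d[2], each = d[1]), nrow = d[1])
    add$date_index <- col
    tags <- c(tags, "date_index")
  }
  if (!is.null(probabilities)) {
    probabilities <- trajectory_labels(probabilities)
    col <- matrix(0, nrow = d[1], ncol = d[2])
    for (i in seq_len(d[1])) {
      p <- probabilities[[panel$patients[i]]]
      if (is.null(p)) stop("no probabilities for patient ", panel$patients[i],
                           call. = FALSE)
      if (length(p) < panel$lengths[i]) {
        stop(sprintf("probability vector for %s has %d days, panel has %d",
                     panel$patients[i], length(p), panel$lengths[i]),
             call. = FALSE)
      }
      L <- panel$lengths[i]
      col[i, seq_len(L)] <- c(p[1], p[seq_len(L - 1L)])
    }
    add$prev_probability <- col
    tags <- c(tags, "injected_probability")
  }
  if (!length(add)) return(panel)
  vals <- array(c(panel$values, unlist(add)),
                dim = c(d[1], d[2], d[3] + length(add)))
  feature_panel(vals, patients = panel$patients,
                features = c(panel$features, names(add)),
                tags = c(panel$tags, tags), lengths = panel$lengths) -> out
  out$imputed <- panel$imputed; out$filled <- panel$filled
  out$norm <- panel$norm; out$log <- panel$log
  out$fill_constant <- panel$fill_constant
  out
}

#' Restrict the modeled day range per patient
#'
#' Implements the four data-range settings: keep everything up to the
#' readmission event (`post_op_to_event`, `post_discharge_to_event` — with
#' panels that start the day after discharge the two coincide), drop rows
#' after the readmission day (`exclude_post_readmission`), or keep the full
#' horizon for everyone (`full_60`, the best-performing setting).
#' Non-readmitted patients always keep their full horizon.
#'
#' @param panel A [feature_panel()].
#' @param metas Named list of [patient_meta()] objects.
#' @param setting One of `"full_60"`, `"post_op_to_event"`,
#'   `"post_discharge_to_event"`, `"exclude_post_readmission"`.
#' @return Panel with per-patient `lengths` updated.
#' @export
select_data_range <- function(panel, metas,
                              setting = c("full_60", "post_op_to_event",
                                          "post_discharge_to_event",
                                          "exclude_post_readmission")) {
  setting <- match.arg(setting)
  stopifnot(inherits(panel, "feature_panel"))
  if (setting == "full_60") return(panel)
  for (i in seq_along(panel$patients)) {
    m <- metas[[panel$patients[i]]]
    if (is.null(m)) stop("no metadata for patient ", panel$patients[i],
                         call. = FALSE)
    if (m$readmitted) {
      panel$lengths[i] <- min(panel$lengths[i], m$readmission_day)
    }
  }
  panel
}

#' Run the standard preprocessing pipeline
#'
#' Convenience wrapper chaining [deviation_features()], [filter_features()],
#' [select_data_range()], [impute_moving_average()] and
#' [normalize_minmax()] with the best-performing defaults: deviation window
#' 7, 80% missingness / 0.3 variance / first-day filters, full-horizon data
#' range, 2-day moving-average imputation with -1 fallback.
#'
#' @param panel Raw [feature_panel()].
#' @param metas Named list of [patient_meta()] (needed for non-default
#'   `data_range`).
#' @param deviation_window Window for deviation features; `0` disables them.
#' @param max_missing_frac,min_variance,drop_if_first_day_missing Filters,
#'   see [filter_features()].
#' @param data_range See [select_data_range()].
#' @param impute_k,fill_constant See [impute_moving_average()].
#' @param sources Which base-feature tags enter the model (any subset of
#'   `sensor`, `symptom`, `deviation`).
#' @return A processed, normalized [feature_panel()].
#' @export
preprocess_panel <- function(panel, metas = NULL, deviation_window = 7L,
                             max_missing_frac = 0.8, min_variance = 0.3,
                             drop_if_first_day_missing = TRUE,
                             data_range = "full_60", impute_k = 2L,
                             fill_constant = -1,
                             sources = c("sensor", "symptom", "deviation")) {
  if (deviation_window > 0 && "deviation" %in% sources) {
    panel <- deviation_features(panel, window = deviation_window)
  }
  keep <- panel$tags %in% sources
  if (!any(keep)) stop("no features left after source selection", call. = FALSE)
  if (!all(keep)) {
    panel <- feature_panel(panel$values[, , keep, drop = FALSE],
                           patients = panel$patients,
                           features = panel$features[keep],
                           tags = panel$tags[keep], lengths = panel$lengths)
  }
  panel <- filter_features(panel, max_missing_frac = max_missing_frac,
                           min_variance = min_variance,
                           drop_if_first_day_missing = drop_if_first_day_missing)
  if (data_range != "full_60") {
    panel <- select_data_range(panel, metas, data_range)
  }
  panel <- impute_moving_average(panel, k_prev = impute_k,
                                 fill_constant = fill_constant)
  normalize_minmax(panel)
}
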