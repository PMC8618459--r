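#' Synthetic cohort specification
#'
#' Describes a simulated post-discharge cohort with the statistical
#' structure of the original study population: roughly one third of
#' patients readmitted, integer LACE/HOSPITAL scores whose initial
#' probabilities spread over \[0.2, 0.8\], 0-10 symptom reports that decay
#' over the 60-day horizon for non-readmitted patients and peak around the
#' readmission day for readmitted ones, and daily sensor features of which
#' a subset tracks the latent risk while the rest is distractor noise.
#'
#' @param n_patients Cohort size (>= 2).
#' @param readmitted_fraction Fraction readmitted within the horizon
#'   (default 0.34, the study's rate; count rounds to nearest).
#' @param horizon Follow-up days (default 60).
#' @param n_sensor_features Daily sensor features; half are signal (affine
#'   in the latent risk), half distractors (pure noise).
#' @param n_symptoms Daily 0-10 symptom reports (default 10).
#' @param symptom_decay_rate Per-day exponential decay of the post-operative
#'   transient added to symptoms (default 0.05/day).
#' @param readmission_peak_gain Extra symptom points (0-10 scale) added in a
#'   bump around the readmission day (default 2).
#' @param feature_signal_strength Scale of the latent-risk component in
#'   signal sensor features relative to their noise (default 0.8; 0 makes
#'   every sensor feature uninformative).
#' @param sensor_encoding How signal sensor features encode the latent risk:
#'   `"level"` (affine in the day's risk — a single day's features suffice)
#'   or `"increment"` (affine in the day-to-day risk *change*, e.g. a drop
#'   in step counts as a patient deteriorates — the level is only
#'   recoverable by integrating the sequence, so per-day models are blind
#'   to it).
#' @param missing_rate Expected fraction of missing cells per
#'   patient/feature, realized half as scattered cells and half as one
#'   contiguous block (default 0.15).
#' @param score_noise SD, in points, of the noise on integer score
#'   emissions — LACE/HOSPITAL draws and daily symptom reports (default 1).
#' @param retain_first_day Force day 1 to be observed for every feature
#'   (default TRUE; the day-1 filter would otherwise discard almost
#'   everything)?
#' @param trajectory A [trajectory_config()] used for the latent risk
#'   (default: exponential function, averaged scores, reset-to-initial).
#' @param seed Master seed; every draw flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 49L, readmitted_fraction = 0.34,
                        horizon = 60L, n_sensor_features = 40L,
                        n_symptoms = 10L, symptom_decay_rate = 0.05,
                        readmission_peak_gain = 2,
                        feature_signal_strength = 0.8,
                        sensor_encoding = c("level", "increment"),
                        missing_rate = 0.15,
                        score_noise = 1, retain_first_day = TRUE,
                        trajectory = trajectory_config(horizon = horizon),
                        seed = 1L) {
  sensor_encoding <- match.arg(sensor_encoding)
  stopifnot(n_patients >= 2, readmitted_fraction >= 0, readmitted_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1, horizon >= 2)
  structure(list(n_patients = as.integer(n_patients),
                 readmitted_fraction = readmitted_fraction,
                 horizon = as.integer(horizon),
                 n_sensor_features = as.integer(n_sensor_features),
                 n_symptoms = as.integer(n_symptoms),
                 symptom_decay_rate = symptom_decay_rate,
                 readmission_peak_gain = readmission_peak_gain,
                 feature_signal_strength = feature_signal_strength,
                 sensor_encoding = sensor_encoding,
                 missing_rate = missing_rate, score_noise = score_noise,
                 retain_first_day = isTRUE(retain_first_day),
                 trajectory = trajectory, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws patient metadata, latent risk trajectories (through the label
#' module, so every label invariant holds by construction), daily symptom
#' reports and sensor features, and applies missingness. Fully seeded:
#' the same spec yields byte-identical output; each patient consumes an
#' independent sub-stream so editing one spec field perturbs patients
#' minimally.
#'
#' @param spec A [cohort_spec()].
#' @return List with `metas` (named list of [patient_meta()]),
#'   `trajectories` (named list of `risk_trajectory`), `panel` (raw
#'   [feature_panel()] with missing cells), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_patients
  H <- spec$horizon
  n_re <- round(n * spec$readmitted_fraction)
  if (spec$readmitted_fraction > 0 && n_re < 1) {
    warning("readmitted fraction rounds to zero patients; cohort is all non-readmitted")
  }
  ids <- sprintf("p%03d", seq_len(n))
  readmit <- ids %in% sample(ids, n_re)
  pat_seed <- sample.int(.Machine$integer.max - n, n)   # per-patient streams

  # feature-level constants shared across patients
  n_sig <- ceiling(spec$n_sensor_features / 2)
  n_noise <- spec$n_sensor_features - n_sig
  scale_j <- 10^stats::runif(spec$n_sensor_features, 0, 2.5)
  sign_j <- sample(c(-1, 1), spec$n_sensor_features, replace = TRUE)
  base_j <- stats::rnorm(spec$n_sensor_features, 0, 1) * scale_j
  gamma_s <- stats::runif(spec$n_symptoms, 0.6, 1.2)
  transient_s <- stats::runif(spec$n_symptoms, 0.5, 2)

  feats <- c(sprintf("symptom_%02d", seq_len(spec$n_symptoms)),
             sprintf("sensor_sig_%02d", seq_len(n_sig)),
             if (n_noise > 0) sprintf("sensor_noise_%02d", seq_len(n_noise)))
  tags <- c(rep("symptom", spec$n_symptoms),
            rep("sensor", spec$n_sensor_features))
  vals <- array(NA_real_, dim = c(n, H, length(feats)),
                dimnames = list(ids, NULL, feats))

  metas <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(pat_seed[i])
    p0 <- stats::runif(1, 0.2, 0.8)
    clampr <- function(x, hi) as.integer(min(hi, max(0, round(x))))
    lace <- clampr(p0 * 19 + stats::rnorm(1, 0, spec$score_noise), 19)
    hosp <- clampr(p0 * 15 + stats::rnorm(1, 0, spec$score_noise), 15)
    if (readmit[i]) {
      kdays <- 5:min(45, H - 10)
      k <- sample(kdays, 1, prob = exp(-0.05 * kdays))
      d2nd <- min(k + sample(3:7, 1), H - 5)
      metas[[i]] <- patient_meta(ids[i], readmitted = TRUE,
                                 readmission_day = k,
                                 second_discharge_day = d2nd,
                                 lace = lace, hospital = hosp)
    } else {
      metas[[i]] <- patient_meta(ids[i], lace = lace, hospital = hosp)
    }
  }
  names(metas) <- ids
  trajectories <- build_trajectories(metas, spec$trajectory)

  for (i in seq_len(n)) {
    set.seed(pat_seed[i] + 1L)
    latent <- trajectories[[i]]$probabilities
    days <- seq_len(H)
    peak <- if (readmit[i]) {
      k <- metas[[i]]$readmission_day
      spec$readmission_peak_gain * exp(-(days - k)^2 / 18)
    } else 0
    for (s in seq_len(spec$n_symptoms)) {
      raw <- 10 * latent * gamma_s[s] +
        transient_s[s] * exp(-spec$symptom_decay_rate * (days - 1)) + peak +
        stats::rnorm(H, 0, spec$score_noise)
      vals[i, , s] <- pmin(10, pmax(0, round(raw)))
    }
    carrier <- if (spec$sensor_encoding == "level") latent
               else c(0, diff(latent)) * 5   # rescale daily changes
    for (j in seq_len(spec$n_sensor_features)) {
      col <- spec$n_symptoms + j
      noise <- stats::rnorm(H, 0, 0.1 * scale_j[j])
      vals[i, , col] <- if (j <= n_sig) {
        base_j[j] + sign_j[j] * scale_j[j] * spec$feature_signal_strength *
          carrier + noise
      } else {
        base_j[j] + 5 * noise
      }
    }
    # missingness: half scattered, half one contiguous block per feature
    if (spec$missing_rate > 0) {
      for (col in seq_along(feats)) {
        drop <- stats::runif(H) < spec$missing_rate / 2
        exp_block <- spec$missing_rate / 2 * H
        if (stats::runif(1) < exp_block / 5) {
          len <- min(H - 1L, 3L + stats::rgeom(1, 1 / 3))
          start <- sample.int(H - len + 1L, 1)
          drop[start:(start + len - 1L)] <- TRUE
        }
        if (spec$retain_first_day) drop[1] <- FALSE
        vals[i, drop, col] <- NA_real_
      }
    }
  }
  panel <- feature_panel(vals, patients = ids, features = feats, tags = tags)
  list(metas = metas, trajectories = trajectories, panel = panel, spec = spec)
}

#' Write a generated cohort to disk
#'
#' Emits exactly the CSV schemas the rest of the package consumes:
#' `meta.csv` ([read_patient_meta()]), `features.csv`
#' ([read_feature_panel()]), `trajectories.csv` ([read_trajectories()]),
#' and a JSON sidecar with the generating spec.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patient_meta(cohort$metas, file.path(dir, "meta.csv"))
  write_feature_panel(cohort$panel, file.path(dir, "features.csv"))
  write_trajectories(cohort$trajectories, file.path(dir, "trajectories.csv"),
                     sidecar = file.path(dir, "segments.json"))
  spec <- cohort$spec
  spec$trajectory <- unclass(spec$trajectory)
  jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run the full pipeline on a synthetic cohort and check recovery
#'
#' Generates a cohort, preprocesses it, trains the leave-one-patient-out
#' LSTM, and reports whether the ground-truth trajectories are recovered
#' (full-horizon all-patient MSE below `mse_bound`). Optionally also fits
#' the three classic baselines and ranks everything together.
#'
#' @param spec A [cohort_spec()].
#' @param config An [lstm_config()].
#' @param mse_bound Recovery bound on the all-patients full-horizon MSE.
#' @param baselines Also fit MLR/RT/SVR and rank?
#' @param k,K Submetric windows.
#' @return List with `fit`, `report`, `mse_full`, `recovered`, and (when
#'   `baselines`) `ranking`.
#' @export
parameter_recovery_suite <- function(spec, config = lstm_config(seed = spec$seed),
                                     mse_bound = 0.02, baselines = FALSE,
                                     k = 20L, K = spec$horizon) {
  cohort <- generate_cohort(spec)
  panel <- preprocess_panel(cohort$panel, cohort$metas)
  fit <- train_lopo(panel, cohort$trajectories, config)
  report <- submetrics(fit$predictions, cohort$metas, k = k, K = K,
                       model_name = "LSTM")
  mse_full <- mse(fit$predictions$y_true, fit$predictions$y_pred)
  out <- list(fit = fit, report = report, mse_full = mse_full,
              recovered = mse_full < mse_bound)
  if (baselines) {
    reports <- list(report)
    for (m in c("MLR", "RT", "SVR")) {
      bfit <- fit_baseline(panel, cohort$trajectories, baseline_config(m),
                           include_date_index = config$include_date_index,
                           seed = spec$seed)
      reports <- c(reports, list(submetrics(bfit$predictions, cohort$metas,
                                            k = k, K = K, model_name = m)))
    }
    out$ranking <- rank_models(reports)
  }
  out
}
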