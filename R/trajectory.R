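#' Initial readmission probability from administrative scores
#'
#' Maps a LACE or HOSPITAL score linearly onto a probability: a score of 0
#' gives probability 0, the maximum score (19 for LACE, 15 for HOSPITAL)
#' gives 1, and intermediate scores scale linearly (LACE 10 -> 10/19 = 0.53).
#' With `source = "average"` the two normalized scores are averaged.
#'
#' @param meta A [patient_meta()] object.
#' @param source One of `"LACE"`, `"HOSPITAL"`, `"average"`.
#' @return A probability in \[0, 1\].
#' @examples
#' m <- patient_meta("p", lace = 10, hospital = 6)
#' initial_probability(m, "LACE")     # 10/19
#' initial_probability(m, "average")  # mean(10/19, 6/15)
#' @export
initial_probability <- function(meta, source = c("average", "LACE", "HOSPITAL")) {
  source <- match.arg(source)
  stopifnot(inherits(meta, "patient_meta"))
  p_lace <- meta$lace / 19
  p_hosp <- meta$hospital / 15
  switch(source,
         LACE = p_lace,
         HOSPITAL = p_hosp,
         average = (p_lace + p_hosp) / 2)
}

#' Risk-trajectory configuration
#'
#' Collects the switches that define how a patient's daily risk-probability
#' label sequence is generated from the initial and final probabilities.
#'
#' @param fun Daily probability function family: `"linear"` (p_n = a n + b),
#'   `"exponential"` (p_n = a^n + b), `"logarithmic"` (p_n = log_a(n) + b) or
#'   `"weighted_linear"` (p_n = w l_n + (1 - w) p_{n-1} with a parabolic
#'   weight, 1 at the segment endpoints).
#' @param initial_source Which score seeds the day-1 probability:
#'   `"LACE"`, `"HOSPITAL"` or their `"average"`.
#' @param readmitted_mode After the second discharge of a readmitted patient
#'   the probability either falls from 1 all the way to 0
#'   (`"continue_from_one"`: held at 1 while in hospital) or is first brought
#'   back down to the initial probability during the readmission stay and
#'   then decays to 0 (`"reset_to_initial"`).
#' @param horizon Number of follow-up days (default 60; risk is taken to be
#'   0 on the final day).
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(fun = c("exponential", "linear", "logarithmic",
                                      "weighted_linear"),
                              initial_source = c("average", "LACE", "HOSPITAL"),
                              readmitted_mode = c("reset_to_initial",
                                                  "continue_from_one"),
                              horizon = 60L) {
  fun <- match.arg(fun)
  initial_source <- match.arg(initial_source)
  readmitted_mode <- match.arg(readmitted_mode)
  horizon <- as.integer(horizon)
  if (horizon < 2L) stop("`horizon` must be >= 2", call. = FALSE)
  structure(list(fun = fun, initial_source = initial_source,
                 readmitted_mode = readmitted_mode, horizon = horizon),
            class = "trajectory_config")
}

# Fit one monotone segment p(d1) = p_start .. p(d2) = p_end for a family.
# Exponential and logarithmic fits are re-indexed to a local day n' = 1..m
# (m = d2 - d1 + 1) so log(0) never arises and the one-parameter solve is
# well posed regardless of where the segment starts.

#' Fit the parameters of one trajectory segment
#'
#' Solves for the two parameters (a, b) of the configured function family so
#' that the segment passes through `p_start` on day `d1` and `p_end` on day
#' `d2`. Exponential segments solve a - a^m = p_start - p_end numerically on
#' the slow branch (a near 1, the gentle decay/rise seen over a 60-day
#' horizon); logarithmic segments have a closed form.
#'
#' @param fun `"linear"`, `"exponential"` or `"logarithmic"`.
#' @param p_start,p_end Probabilities at the segment endpoints.
#' @param d1,d2 First and last day index of the segment (`d2 > d1`).
#' @return A list with elements `fun`, `a`, `b`, `d1`, `d2`, `degenerate`.
#'   Parameters are in the local index n' = n - d1 + 1.
#' @export
fit_segment <- function(fun, p_start, p_end, d1, d2) {
  stopifnot(p_start >= 0, p_start <= 1, p_end >= 0, p_end <= 1)
  d1 <- as.integer(d1); d2 <- as.integer(d2)
  if (d2 <= d1) stop("`d2` must exceed `d1`", call. = FALSE)
  m <- d2 - d1 + 1L
  out <- list(fun = fun, d1 = d1, d2 = d2, degenerate = FALSE)
  if (fun == "linear") {
    a <- (p_end - p_start) / (m - 1)
    out$a <- a
    out$b <- p_start - a   # p(n') = a n' + b, n' = 1..m
    return(out)
  }
  if (p_start == p_end) {  # flat segment: a^n / log_a n degenerate
    out$degenerate <- TRUE
    out$a <- NA_real_
    out$b <- p_start
    return(out)
  }
  if (fun == "exponential") {
    dp <- p_start - p_end
    if (dp > 0) {
      # falling: a in (0,1) with a - a^m = dp; two roots exist, keep the
      # slow-decay branch right of the maximum of a - a^m
      a_peak <- (1 / m)^(1 / (m - 1))
      peak_val <- a_peak - a_peak^m
      if (dp > peak_val) {
        # the family p = a^n + b cannot drop this far in m days (its maximum
        # drop is max_a a - a^m); short steep segments fall back to linear
        out <- fit_segment("linear", p_start, p_end, d1, d2)
        out$fallback_from <- "exponential"
        return(out)
      }
      f <- function(a) a - a^m - dp
      a <- stats::uniroot(f, c(a_peak, 1 - 1e-12), tol = 1e-14)$root
    } else {
      f <- function(a) a^m - a + dp   # rising: a > 1
      upper <- 2
      while (f(upper) < 0) upper <- upper * 2
      a <- stats::uniroot(f, c(1 + 1e-12, upper), tol = 1e-14)$root
    }
    out$a <- a
    out$b <- p_end - a^m
    return(out)
  }
  if (fun == "logarithmic") {
    # p(n') = log_a(n') + b: p(1) = b, p(m) = log(m)/log(a) + b
    out$b <- p_start
    out$a <- exp(log(m) / (p_end - p_start))
    return(out)
  }
  stop("unknown segment function: ", fun, call. = FALSE)
}

#' Evaluate a fitted segment over its days
#'
#' @param seg A segment from [fit_segment()].
#' @return Numeric vector of probabilities for days `d1..d2`.
#' @export
eval_segment <- function(seg) {
  m <- seg$d2 - seg$d1 + 1L
  n <- seq_len(m)
  if (seg$degenerate) return(rep(seg$b, m))
  p <- switch(seg$fun,
              linear = seg$a * n + seg$b,
              exponential = seg$a^n + seg$b,
              logarithmic = log(n, base = seg$a) + seg$b,
              stop("unknown segment function: ", seg$fun, call. = FALSE))
  pmin(1, pmax(0, p))
}

#' Parabolic weights of the weighted linear function
#'
#' w_n = 4/(d1 - d2)^2 (n - (d1 + d2)/2)^2 for n in `d1..d2`: exactly 1 at
#' both segment endpoints and 0 at the midpoint (when the midpoint lands on
#' an integer day).
#'
#' @param d1,d2 Segment endpoints, `d2 > d1`.
#' @return Numeric vector of weights, one per day `d1..d2`, all in \[0, 1\].
#' @export
weighted_linear_weights <- function(d1, d2) {
  if (d2 <= d1) stop("`d2` must exceed `d1`", call. = FALSE)
  n <- d1:d2
  4 / (d1 - d2)^2 * (n - (d1 + d2) / 2)^2
}

#' Weighted linear trajectory segment
#'
#' Blends the plain linear interpolant l_n with the previous day's value:
#' p_n = w_n l_n + (1 - w_n) p_{n-1}. Because w = 1 on day `d1`, the first
#' day equals the linear value (no dependence on an undefined p_{d1 - 1}),
#' and w = 1 on day `d2` pins the endpoint to `p_end`.
#'
#' @inheritParams fit_segment
#' @return Numeric vector of probabilities for days `d1..d2`.
#' @export
weighted_linear_segment <- function(p_start, p_end, d1, d2) {
  lin <- eval_segment(fit_segment("linear", p_start, p_end, d1, d2))
  w <- weighted_linear_weights(d1, d2)
  p <- numeric(length(w))
  p[1] <- lin[1]
  for (i in seq_along(w)[-1]) {
    p[i] <- w[i] * lin[i] + (1 - w[i]) * p[i - 1]
  }
  pmin(1, pmax(0, p))
}

segment_values <- function(fun, p_start, p_end, d1, d2) {
  if (fun == "weighted_linear") {
    list(values = weighted_linear_segment(p_start, p_end, d1, d2),
         params = list(fun = fun, d1 = d1, d2 = d2,
                       p_start = p_start, p_end = p_end))
  } else {
    seg <- fit_segment(fun, p_start, p_end, d1, d2)
    list(values = eval_segment(seg), params = seg)
  }
}

#' Build the daily risk-probability trajectory for one patient
#'
#' Expands a patient's initial probability (from LACE/HOSPITAL) into the full
#' per-day label sequence p_1..p_horizon:
#' \itemize{
#'   \item non-readmitted: one falling segment from the initial probability
#'     on day 1 to 0 on the final day;
#'   \item readmitted, `continue_from_one`: rises from the initial
#'     probability to 1 on the readmission day, stays at 1 until the second
#'     discharge, then falls from 1 to 0;
#'   \item readmitted, `reset_to_initial`: rises to 1 on the readmission day,
#'     falls back to the initial probability during the readmission stay,
#'     then falls from the initial probability to 0.
#' }
#' All segments use the configured function family; values are clamped to
#' \[0, 1\] and the final day is exactly 0.
#'
#' @param meta A [patient_meta()] object.
#' @param config A [trajectory_config()].
#' @return An object of class `risk_trajectory`: list with `patient_id`,
#'   `probabilities` (length `horizon`), `initial`, `segments` (fitted
#'   parameters per segment) and `config`.
#' @export
build_trajectory <- function(meta, config = trajectory_config()) {
  stopifnot(inherits(meta, "patient_meta"), inherits(config, "trajectory_config"))
  H <- config$horizon
  p0 <- initial_probability(meta, config$initial_source)
  p <- numeric(H)
  segs <- list()
  put <- function(p, seg, d1) {
    p[d1:(d1 + length(seg) - 1L)] <- seg
    p
  }
  if (!meta$readmitted) {
    s <- segment_values(config$fun, p0, 0, 1L, H)
    p <- put(p, s$values, 1L)
    segs <- list(fall = s$params)
  } else {
    k <- meta$readmission_day
    d2nd <- meta$second_discharge_day
    if (k >= H) stop("`readmission_day` must precede the horizon", call. = FALSE)
    if (d2nd > H) stop("`second_discharge_day` must not exceed the horizon",
                       call. = FALSE)
    rise <- segment_values(config$fun, p0, 1, 1L, k)
    p <- put(p, rise$values, 1L)
    if (config$readmitted_mode == "continue_from_one") {
      p[k:d2nd] <- 1
      fall <- segment_values(config$fun, 1, 0, d2nd, H)
      p <- put(p, fall$values, d2nd)
      segs <- list(rise = rise$params, hold = list(fun = "constant", value = 1,
                                                   d1 = k, d2 = d2nd),
                   fall = fall$params)
    } else {
      inhosp <- segment_values(config$fun, 1, p0, k, d2nd)
      p <- put(p, inhosp$values, k)
      fall <- segment_values(config$fun, p0, 0, d2nd, H)
      p <- put(p, fall$values, d2nd)
      segs <- list(rise = rise$params, reset = inhosp$params, fall = fall$params)
    }
  }
  p <- pmin(1, pmax(0, p))
  p[H] <- 0
  structure(list(patient_id = meta$patient_id, probabilities = p,
                 initial = p0, segments = segs, config = config),
            class = "risk_trajectory")
}

#' Build trajectories for a whole cohort
#'
#' @param metas Named list of [patient_meta()] objects.
#' @param config A [trajectory_config()] shared by all patients.
#' @return Named list of `risk_trajectory` objects.
#' @export
build_trajectories <- function(metas, config = trajectory_config()) {
  out <- lapply(metas, build_trajectory, config = config)
  names(out) <- vapply(metas, `[[`, "", "patient_id")
  out
}

#' @export
print.risk_trajectory <- function(x, ...) {
  p <- x$probabilities
  cat(sprintf("<risk_trajectory> %s  %s over %d days: p1=%.3f .. p%d=%.3f\n",
              x$patient_id, x$config$fun, length(p), p[1], length(p),
              p[length(p)]))
  invisible(x)
}

#' Write / read cohort trajectories as CSV (+ JSON segment sidecar)
#'
#' The CSV holds one row per patient-day (`patient_id`, `day`,
#' `probability`); the optional JSON sidecar records the fitted segment
#' parameters and configuration per patient.
#'
#' @param trajectories Named list of `risk_trajectory` objects.
#' @param path Output CSV path.
#' @param sidecar Optional JSON path for segment parameters.
#' @export
write_trajectories <- function(trajectories, path, sidecar = NULL) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(patient_id = tr$patient_id,
               day = seq_along(tr$probabilities),
               probability = tr$probabilities)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- lapply(trajectories, function(tr) {
      list(initial = tr$initial, config = unclass(tr$config),
           segments = lapply(tr$segments, function(s) s[!vapply(s, is.null, TRUE)]))
    })
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trajectories
#' @return `read_trajectories()` returns a named list of per-patient
#'   probability vectors.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_ids <- split(df, df$patient_id)
  lapply(split_ids, function(d) d$probability[order(d$day)])
}

#' Extract plain probability vectors from trajectory objects
#'
#' @param trajectories Named list of `risk_trajectory` objects (or already
#'   plain numeric vectors, returned unchanged).
#' @return Named list of numeric vectors.
#' @export
trajectory_labels <- function(trajectories) {
  lapply(trajectories, function(tr) {
    if (inherits(tr, "risk_trajectory")) tr$probabilities else tr
  })
}
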