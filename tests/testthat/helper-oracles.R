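# Independent oracles: deliberately brute-force / literal re-implementations
# used to check the package's faster or more general code paths.

# bisection on a - a^m = dp (falling exponential segment, slow branch)
oracle_exp_falling_a <- function(p_start, p_end, m, tol = 1e-12) {
  dp <- p_start - p_end
  f <- function(a) a - a^m - dp
  lo <- (1 / m)^(1 / (m - 1))   # argmax of a - a^m
  hi <- 1 - 1e-12
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# bisection on a^m - a = dp (rising exponential segment, a > 1)
oracle_exp_rising_a <- function(p_start, p_end, m, tol = 1e-12) {
  dp <- p_end - p_start
  f <- function(a) a^m - a - dp
  lo <- 1 + 1e-12; hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# literal day-by-day recursion of the weighted linear function
oracle_weighted_linear <- function(p_start, p_end, d1, d2) {
  lin_a <- (p_end - p_start) / (d2 - d1)
  lin <- function(n) lin_a * (n - d1) + p_start
  w <- function(n) 4 / (d1 - d2)^2 * (n - (d1 + d2) / 2)^2
  p <- numeric(d2 - d1 + 1)
  p[1] <- lin(d1)
  for (n in (d1 + 1):d2) {
    i <- n - d1 + 1
    p[i] <- w(n) * lin(n) + (1 - w(n)) * p[i - 1]
  }
  p
}

# brute-force rank-and-sum point system (average ties), on a models x metrics
# matrix with named columns; direction: ascending for mse_*, descending cov_*
oracle_points <- function(M) {
  nm <- nrow(M)
  pts <- rep(0, nm)
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    if (startsWith(colnames(M)[j], "cov")) x <- -x
    # explicit average-tie ranking by enumeration
    r <- vapply(seq_len(nm), function(i) {
      less <- sum(x < x[i])
      ties <- sum(x == x[i])
      less + (ties + 1) / 2
    }, 0)
    pts <- pts + (nm - r) / (nm - 1)
  }
  pts
}

# slice-by-slice recomputation of the 12 submetrics from raw prediction rows
oracle_submetrics <- function(pred, readmitted, k, K) {
  out <- numeric(0)
  sel_sets <- list(all = rep(TRUE, nrow(pred)),
                   nonreadmitted = !readmitted[as.character(pred$patient_id)],
                   readmitted = readmitted[as.character(pred$patient_id)])
  for (metric in c("mse", "cov")) {
    for (win in c("first", "full")) {
      lim <- if (win == "first") k else K
      for (sn in names(sel_sets)) {
        sel <- sel_sets[[sn]] & pred$day <= lim
        nm <- sprintf("%s_%s%d_%s", metric, win, lim, sn)
        y <- pred$y_true[sel]; yh <- pred$y_pred[sel]
        out[nm] <- if (sum(sel) < 2) NA_real_
          else if (metric == "mse") mean((y - yh)^2)
          else sum((y - mean(y)) * (yh - mean(yh))) / (length(y) - 1)
      }
    }
  }
  out
}

# hand-built toy panel: values[patient, day, feature]
toy_panel <- function(values, tags = NULL, patients = NULL) {
  feature_panel(values, patients = patients, tags = tags)
}

# tiny fully synthetic cohort for fast model tests
tiny_cohort <- function(n = 6, seed = 42, n_sensor = 4, signal = 1,
                        missing = 0, noise = 0.5) {
  generate_cohort(cohort_spec(n_patients = n, n_sensor_features = n_sensor,
                              n_symptoms = 3, feature_signal_strength = signal,
                              missing_rate = missing, score_noise = noise,
                              seed = seed))
}

# literal R re-implementation of the stacked-LSTM forward pass (the C++ path
# is checked against this on tiny inputs)
oracle_lstm_forward <- function(params, X) {
  sig <- function(z) 1 / (1 + exp(-z))
  Fdim <- dim(X)[1]; P <- dim(X)[2]; Tn <- dim(X)[3]
  L <- params$n_layers
  h <- lapply(seq_len(L), function(l) matrix(0, ncol(params$U[[l]]), P))
  cs <- h
  yhat <- matrix(0, Tn, P)
  for (t in seq_len(Tn)) {
    input <- matrix(X[, , t], ncol = P)
    for (l in seq_len(L)) {
      H <- ncol(params$U[[l]])
      a <- params$W[[l]] %*% input + params$U[[l]] %*% h[[l]] + params$b[[l]]
      i <- sig(a[1:H, , drop = FALSE])
      f <- sig(a[(H + 1):(2 * H), , drop = FALSE])
      g <- tanh(a[(2 * H + 1):(3 * H), , drop = FALSE])
      o <- sig(a[(3 * H + 1):(4 * H), , drop = FALSE])
      cs[[l]] <- f * cs[[l]] + i * g
      h[[l]] <- o * tanh(cs[[l]])
      input <- h[[l]]
    }
    yhat[t, ] <- sig(drop(crossprod(params$v, h[[L]])) + params$c0)
  }
  yhat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
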