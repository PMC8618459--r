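#' Baseline model configuration
#'
#' Classic per-day regressors used for comparison with the sequence model:
#' multiple linear regression (MLR), a CART regression tree (RT), and
#' support-vector regression (SVR). They see exactly the same processed
#' feature rows as the LSTM but one day at a time — no sequence structure
#' and no previous-day probability — so they predict the risk of a day from
#' that day's features alone.
#'
#' @param method `"MLR"`, `"RT"` or `"SVR"`.
#' @param hyperparameters Named list overriding the pinned defaults
#'   (recorded in the fit's manifest): RT — `max_depth` (Inf),
#'   `min_split` (2), `min_bucket` (1); SVR — `C` (1), `epsilon` (0.1),
#'   `gamma` (`NULL` = 1/(d Var X)), `max_train_rows` (600). MLR has none.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(method = c("MLR", "RT", "SVR"),
                            hyperparameters = list()) {
  method <- match.arg(method)
  defaults <- switch(method,
    MLR = list(),
    RT = list(max_depth = Inf, min_split = 2L, min_bucket = 1L),
    SVR = list(C = 1, epsilon = 0.1, gamma = NULL, max_train_rows = 600L))
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop("unknown ", method, " hyperparameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(method = method, hyperparameters = defaults),
            class = "baseline_config")
}

# panel -> pooled per-day rows (X matrix, y vector, patient/day bookkeeping)
panel_rows <- function(panel, labels) {
  d <- dim(panel$values)
  rows <- lapply(seq_len(d[1]), function(i) {
    L <- panel$lengths[i]
    X <- matrix(panel$values[i, seq_len(L), , drop = TRUE], nrow = L,
                dimnames = list(NULL, panel$features))
    data.frame(patient_id = panel$patients[i], day = seq_len(L),
               y = labels[[panel$patients[i]]][seq_len(L)], X,
               check.names = FALSE)
  })
  do.call(rbind, rows)
}

fit_one_baseline <- function(config, X, y, seed = 1L) {
  switch(config$method,
    MLR = {
      fit <- stats::lm.fit(cbind(1, X), y)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0     # collinear/constant columns contribute 0
      list(predict = function(newX) as.numeric(cbind(1, newX) %*% coefs))
    },
    RT = {
      hp <- config$hyperparameters
      tree <- cart_fit(X, y, max_depth = hp$max_depth,
                       min_split = hp$min_split, min_bucket = hp$min_bucket)
      list(predict = function(newX) predict(tree, newX))
    },
    SVR = {
      hp <- config$hyperparameters
      m <- svr_fit(X, y, C = hp$C, epsilon = hp$epsilon, gamma = hp$gamma,
                   max_train_rows = hp$max_train_rows, seed = seed)
      list(predict = function(newX) predict(m, newX))
    })
}

#' Fit a per-day baseline regressor leave-one-patient-out
#'
#' Pools all training patients' days into flat rows, fits the configured
#' regressor, and predicts every day of the held-out patient. Raw outputs of
#' MLR/RT/SVR can leave \[0, 1\]; since the labels are probabilities the
#' predictions are clipped to \[0, 1\] for evaluation (the raw values are
#' kept in a `y_raw` column).
#'
#' @param panel Processed [feature_panel()] (imputed, normalized; no
#'   injected-probability column).
#' @param trajectories Named list of `risk_trajectory` objects or label
#'   vectors.
#' @param config A [baseline_config()].
#' @param lopo Use leave-one-patient-out (default); `FALSE` fits one model
#'   on everyone and predicts in-sample (for diagnostics only).
#' @param include_date_index Give the baseline the normalized day-index
#'   column (the only sequence information it may see)?
#' @param seed Seed for any subsampling inside the fit.
#' @return List with `predictions` (data frame `patient_id`, `day`,
#'   `y_true`, `y_pred`, `y_raw`, `fold`, `method`) and `config`.
#' @export
fit_baseline <- function(panel, trajectories, config = baseline_config("MLR"),
                         lopo = TRUE, include_date_index = FALSE, seed = 1L) {
  stopifnot(inherits(panel, "feature_panel"), inherits(config, "baseline_config"))
  if ("injected_probability" %in% panel$tags) {
    stop("baselines must not receive the injected-probability column",
         call. = FALSE)
  }
  labels <- trajectory_labels(trajectories)
  if (include_date_index && !"date_index" %in% panel$features) {
    panel <- attach_auxiliary(panel, date_index = TRUE)
  }
  rows <- panel_rows(panel, labels)
  feat_cols <- setdiff(names(rows), c("patient_id", "day", "y"))
  X <- as.matrix(rows[, feat_cols, drop = FALSE])
  folds <- if (lopo) unique(rows$patient_id) else "all"
  if (lopo && length(folds) < 2) {
    stop("leave-one-patient-out needs at least two patients", call. = FALSE)
  }
  preds <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    if (lopo) {
      test <- rows$patient_id == folds[fi]
      train <- !test
    } else {
      test <- train <- rep(TRUE, nrow(rows))
    }
    m <- fit_one_baseline(config, X[train, , drop = FALSE], rows$y[train],
                          seed = seed + fi - 1L)
    raw <- m$predict(X[test, , drop = FALSE])
    preds[[fi]] <- data.frame(patient_id = rows$patient_id[test],
                              day = rows$day[test],
                              y_true = rows$y[test],
                              y_pred = pmin(1, pmax(0, raw)),
                              y_raw = raw, fold = fi,
                              method = config$method)
  }
  list(predictions = do.call(rbind, preds), config = config)
}
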