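#' LSTM model configuration
#'
#' All switches of the recurrent model: depth, width, optimizer, early
#' stopping, and how the previous day's probability is fed back into the
#' input ("injection").
#'
#' @param n_layers 1 or 2 recurrent layers (default 2).
#' @param hidden_units Units per recurrent layer; `NULL` (auto) sets it to
#'   the number of input features.
#' @param learning_rate Adam learning rate (default 0.01).
#' @param max_epochs Upper bound on training epochs (one full-batch update
#'   per epoch).
#' @param patience Early stopping: training halts once the training loss has
#'   not decreased for this many consecutive epochs (default 50); the
#'   weights of the best epoch are kept.
#' @param injection `"none"`, `"actual_prev"` (the true previous-day
#'   probability, available when scores are known, enters as a feature) or
#'   `"predicted_prev"` (the model's own previous prediction is fed back;
#'   teacher-forced with the true labels during training, autoregressive at
#'   inference — the deployable setting).
#' @param include_date_index Append the normalized day index as a feature?
#' @param seed Integer seed for weight initialization.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(n_layers = 2L, hidden_units = NULL,
                        learning_rate = 0.01, max_epochs = 300L,
                        patience = 50L,
                        injection = c("predicted_prev", "actual_prev", "none"),
                        include_date_index = TRUE, seed = 1L) {
  injection <- match.arg(injection)
  stopifnot(n_layers %in% c(1L, 2L), learning_rate > 0, patience >= 1,
            max_epochs >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_units = if (is.null(hidden_units)) NULL
                                else as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 injection = injection,
                 include_date_index = isTRUE(include_date_index),
                 seed = as.integer(seed)),
            class = "lstm_config")
}

# Glorot-uniform initial weights, drawn from R's RNG so `seed` governs the
# whole train/predict cycle; forget-gate biases start at 1.
init_lstm_params <- function(n_features, hidden, n_layers, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  W <- list(); U <- list(); b <- list()
  fin <- n_features
  for (l in seq_len(n_layers)) {
    H <- hidden
    W[[l]] <- glorot(4 * H, fin)
    U[[l]] <- glorot(4 * H, H)
    bias <- rep(0, 4 * H)
    bias[(H + 1):(2 * H)] <- 1
    b[[l]] <- bias
    fin <- H
  }
  list(n_layers = n_layers, W = W, U = U, b = b,
       v = as.numeric(glorot(hidden, 1)), c0 = 0)
}

#' Build an untrained LSTM
#'
#' @param config An [lstm_config()].
#' @param n_features Number of input columns (including any date-index or
#'   injected-probability column).
#' @return An object of class `readmit_lstm` holding the seeded initial
#'   weights.
#' @export
build_lstm <- function(config, n_features) {
  stopifnot(inherits(config, "lstm_config"), n_features >= 1)
  hidden <- if (is.null(config$hidden_units)) n_features else config$hidden_units
  params <- init_lstm_params(n_features, hidden, config$n_layers, config$seed)
  structure(list(params = params, config = config, n_features = n_features,
                 hidden = hidden, trained = FALSE, features = NULL,
                 loss_history = NULL),
            class = "readmit_lstm")
}

#' @export
print.readmit_lstm <- function(x, ...) {
  cat(sprintf("<readmit_lstm> %d layer(s) x %d units, %d inputs, %s\n",
              x$params$n_layers, x$hidden, x$n_features,
              if (x$trained)
                sprintf("trained (best epoch %d, loss %.4f)",
                        x$best_epoch, x$best_loss)
              else "untrained"))
  invisible(x)
}

# panel -> cube of inputs (F x P x T) and matrices of targets/mask (T x P)
# for next-day prediction: inputs are days 1..L-1, targets days 2..L.
sequence_arrays <- function(panel, labels, patients = panel$patients) {
  idx <- match(patients, panel$patients)
  H <- dim(panel$values)[2]
  Tn <- H - 1L
  Fc <- length(panel$features)
  X <- aperm(panel$values[idx, seq_len(Tn), , drop = FALSE], c(3, 1, 2))
  Y <- matrix(0, Tn, length(idx))
  M <- matrix(0, Tn, length(idx))
  for (j in seq_along(idx)) {
    p <- labels[[patients[j]]]
    L <- panel$lengths[idx[j]]
    Y[seq_len(L - 1L), j] <- p[2:L]
    M[seq_len(L - 1L), j] <- 1
  }
  list(X = X, Y = Y, M = M)
}

#' Train an LSTM on a set of patient sequences
#'
#' Trains by full-batch truncated-horizon BPTT: every patient's sequence is
#' one sample, all sequences advance in lockstep, and one Adam step is taken
#' per epoch on the mean absolute error over all observed patient-days.
#'
#' @param model A [build_lstm()] object.
#' @param panel Processed [feature_panel()] including any auxiliary columns.
#' @param labels Named list of per-day probability vectors (or
#'   `risk_trajectory` objects).
#' @param patients Which patients to train on (default: all in the panel).
#' @return The trained `readmit_lstm` (weights of the best epoch).
#' @export
train_lstm <- function(model, panel, labels, patients = panel$patients) {
  stopifnot(inherits(model, "readmit_lstm"))
  labels <- trajectory_labels(labels)
  arr <- sequence_arrays(panel, labels, patients)
  if (dim(arr$X)[1] != model$n_features) {
    stop(sprintf("model expects %d features, panel has %d",
                 model$n_features, dim(arr$X)[1]), call. = FALSE)
  }
  fit <- lstm_train_cpp(model$params, arr$X, arr$Y, arr$M,
                        model$config$learning_rate, model$config$max_epochs,
                        model$config$patience)
  model$params <- fit$params
  model$trained <- TRUE
  model$loss_history <- fit$loss_history
  model$best_epoch <- fit$best_epoch
  model$best_loss <- fit$best_loss
  model$features <- panel$features
  model
}

#' Predict one patient's daily risk trajectory
#'
#' Day 1 is the initial probability (known at discharge from the
#' administrative scores); days 2..L are the model's next-day predictions.
#' Under `predicted_prev` injection the rollout is autoregressive: each
#' day's prediction is written into the injected-probability input of the
#' next day.
#'
#' @param model A trained `readmit_lstm`.
#' @param panel Processed [feature_panel()] containing the patient.
#' @param patient_id Which patient to predict.
#' @param initial The day-1 probability used to seed the trajectory (and the
#'   day-1 injected input).
#' @return Numeric vector of length `panel$lengths[patient]` with one
#'   probability per day.
#' @export
predict_trajectory <- function(model, panel, patient_id, initial) {
  stopifnot(inherits(model, "readmit_lstm"), model$trained)
  i <- match(patient_id, panel$patients)
  if (is.na(i)) stop("patient ", patient_id, " not in panel", call. = FALSE)
  L <- panel$lengths[i]
  if (L < 2) stop("patient ", patient_id, " has fewer than 2 days", call. = FALSE)
  Xp <- t(panel$values[i, seq_len(L - 1L), , drop = TRUE])
  if (is.null(dim(Xp))) Xp <- matrix(Xp, nrow = 1)
  inj <- -1L
  if (model$config$injection == "predicted_prev") {
    j <- match("prev_probability", panel$features)
    if (is.na(j)) stop("panel lacks the `prev_probability` column", call. = FALSE)
    Xp[j, 1] <- initial
    inj <- j - 1L
  }
  yhat <- as.numeric(lstm_predict_cpp(model$params, Xp, inj))
  c(initial, yhat)
}

#' Leave-one-patient-out training and prediction
#'
#' For every patient, trains one model on all other patients' sequences and
#' predicts the held-out patient's daily trajectory, so each prediction
#' comes from a model that never saw that patient. Injection columns are
#' handled internally: the true labels are teacher-forced during training
#' for both injection modes; at inference `actual_prev` reads the known
#' labels while `predicted_prev` rolls out autoregressively.
#'
#' @param panel Processed [feature_panel()] (filtered, imputed, normalized;
#'   without auxiliary columns — they are attached here).
#' @param trajectories Named list of `risk_trajectory` objects (the labels).
#' @param config An [lstm_config()].
#' @return List with `predictions` (data frame `patient_id`, `day`,
#'   `y_true`, `y_pred`, `fold`), `models`, and `config`.
#' @export
train_lopo <- function(panel, trajectories, config = lstm_config()) {
  stopifnot(inherits(panel, "feature_panel"))
  if (length(panel$patients) < 2) {
    stop("leave-one-patient-out needs at least two patients", call. = FALSE)
  }
  labels <- trajectory_labels(trajectories)
  miss <- setdiff(panel$patients, names(labels))
  if (length(miss)) stop("no trajectory for patient(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  initials <- vapply(panel$patients, function(p) labels[[p]][1], 0)
  aug <- attach_auxiliary(panel, date_index = config$include_date_index,
                          probabilities = if (config$injection != "none")
                            labels else NULL)
  nfeat <- length(aug$features)
  preds <- vector("list", length(aug$patients))
  models <- vector("list", length(aug$patients))
  for (i in seq_along(aug$patients)) {
    pid <- aug$patients[i]
    fold_cfg <- config
    fold_cfg$seed <- config$seed + i - 1L
    model <- build_lstm(fold_cfg, nfeat)
    model <- train_lstm(model, aug, labels,
                        patients = setdiff(aug$patients, pid))
    yhat <- predict_trajectory(model, aug, pid, initial = initials[[pid]])
    L <- aug$lengths[i]
    preds[[i]] <- data.frame(patient_id = pid, day = seq_len(L),
                             y_true = labels[[pid]][seq_len(L)],
                             y_pred = yhat, fold = i)
    models[[i]] <- model
  }
  names(models) <- aug$patients
  list(predictions = do.call(rbind, preds), models = models, config = config)
}

#' Write leave-one-patient-out predictions and training logs
#'
#' @param fit Result of [train_lopo()] (or a baseline fit with the same
#'   `predictions` schema).
#' @param path Prediction CSV path.
#' @param log_path Optional CSV of per-fold training-loss histories.
#' @export
write_predictions <- function(fit, path, log_path = NULL) {
  utils::write.csv(fit$predictions, path, row.names = FALSE)
  if (!is.null(log_path) && !is.null(fit$models)) {
    logs <- do.call(rbind, lapply(names(fit$models), function(p) {
      lh <- fit$models[[p]]$loss_history
      if (is.null(lh)) return(NULL)
      data.frame(patient_id = p, epoch = seq_along(lh), loss = lh)
    }))
    utils::write.csv(logs, log_path, row.names = FALSE)
  }
  invisible(path)
}
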