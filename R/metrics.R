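#' Error and association metrics
#'
#' `mae_loss()` is the training criterion (mean absolute error); `mse()` and
#' `covariance()` are the evaluation metrics. Covariance is the sample
#' covariance (n - 1 denominator) between the actual risk (independent
#' variable) and the predicted risk (dependent variable), pooled over all
#' patient-days in the evaluated slice; a model whose predictions move with
#' the actual risk scores high even if offset.
#'
#' @param y Actual probabilities.
#' @param yhat Predicted probabilities (same length as `y`).
#' @return A single number.
#' @export
mae_loss <- function(y, yhat) {
  if (!length(y) || length(y) != length(yhat)) {
    stop("`y` and `yhat` must be nonempty vectors of equal length", call. = FALSE)
  }
  mean(abs(y - yhat))
}

#' @rdname mae_loss
#' @export
mse <- function(y, yhat) {
  if (!length(y) || length(y) != length(yhat)) {
    stop("`y` and `yhat` must be nonempty vectors of equal length", call. = FALSE)
  }
  mean((y - yhat)^2)
}

#' @rdname mae_loss
#' @export
covariance <- function(y, yhat) {
  if (length(y) < 2 || length(y) != length(yhat)) {
    stop("`covariance` needs two equal-length vectors of length >= 2",
         call. = FALSE)
  }
  stats::cov(y, yhat)
}

#' The twelve evaluation submetrics of one model
#'
#' Splits pooled patient-day predictions into six slices — \{all patients,
#' readmitted only, non-readmitted only\} x \{first `k` days, all `K` days\}
#' — and computes MSE and covariance on each. Separating the early window
#' rewards models that are accurate in the first days after discharge, when
#' readmission risk is highest.
#'
#' @param predictions Data frame with columns `patient_id`, `day`, `y_true`,
#'   `y_pred` (the schema emitted by [train_lopo()] and [fit_baseline()]).
#' @param metas Named list of [patient_meta()] objects (supplies readmission
#'   status per patient).
#' @param k Early-window length in days (default 20).
#' @param K Full-window length in days (default 60).
#' @param model_name Label carried into ranking tables.
#' @return An object of class `evaluation_report`: list with `model_name`,
#'   `k`, `K`, and `submetrics`, a named numeric vector of length 12 (names
#'   like `mse_first20_readmitted`); slices with no patients are `NA`.
#' @export
submetrics <- function(predictions, metas, k = 20L, K = 60L,
                       model_name = "model") {
  need <- c("patient_id", "day", "y_true", "y_pred")
  if (!all(need %in% names(predictions))) {
    stop("`predictions` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  readmitted <- vapply(metas, `[[`, TRUE, "readmitted")
  pid <- as.character(predictions$patient_id)
  if (!all(pid %in% names(readmitted))) {
    stop("predictions contain patients absent from `metas`", call. = FALSE)
  }
  is_r <- readmitted[pid]
  strata <- list(all = rep(TRUE, nrow(predictions)),
                 nonreadmitted = !is_r,
                 readmitted = is_r)
  windows <- list(first = predictions$day <= k, full = predictions$day <= K)
  out <- numeric(0)
  for (metric in c("mse", "cov")) {
    for (wn in names(windows)) {
      for (sn in names(strata)) {
        sel <- strata[[sn]] & windows[[wn]]
        nm <- sprintf("%s_%s%d_%s", metric, wn, if (wn == "first") k else K, sn)
        out[nm] <- if (sum(sel) >= 2) {
          y <- predictions$y_true[sel]; yh <- predictions$y_pred[sel]
          if (metric == "mse") mse(y, yh) else covariance(y, yh)
        } else NA_real_
      }
    }
  }
  structure(list(model_name = model_name, k = as.integer(k), K = as.integer(K),
                 submetrics = out),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (k=%d, K=%d)\n", x$model_name, x$k, x$K))
  print(round(x$submetrics, 4))
  invisible(x)
}

#' Rank competing models by the composite point system
#'
#' Every submetric column is ranked across models — MSE ascending (smaller
#' is better), covariance descending (larger is better), ties receiving the
#' average of the tied rank positions. A model earns
#' (nm - Rank) / (nm - 1) points per metric, where nm is the number of
#' models, so the best model on a metric earns 1 and the worst 0; Points are
#' summed over the 12 metrics and the final ranking orders Points from
#' largest to smallest.
#'
#' @param reports List of `evaluation_report` objects (>= 2), or a numeric
#'   matrix of submetrics (models x metrics) with column names starting
#'   `mse_`/`cov_`.
#' @return Data frame with one row per model: the submetrics, `point` and
#'   `final_rank` (1 = best).
#' @export
rank_models <- function(reports) {
  if (is.matrix(reports)) {
    M <- reports
    model_names <- rownames(M)
    if (is.null(model_names)) model_names <- sprintf("model%d", seq_len(nrow(M)))
  } else {
    if (length(reports) < 2) stop("need at least two models to rank", call. = FALSE)
    sets <- lapply(reports, function(r) names(r$submetrics))
    if (!all(vapply(sets, identical, TRUE, sets[[1]]))) {
      stop("reports carry inconsistent submetric sets", call. = FALSE)
    }
    M <- do.call(rbind, lapply(reports, `[[`, "submetrics"))
    model_names <- vapply(reports, `[[`, "", "model_name")
  }
  nm <- nrow(M)
  if (nm < 2) stop("need at least two models to rank", call. = FALSE)
  usable <- colSums(is.na(M)) == 0   # strata absent everywhere drop out
  if (any(!usable & colSums(is.na(M)) < nm)) {
    bad <- colnames(M)[!usable & colSums(is.na(M)) < nm]
    stop("metrics defined for only some models: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  points <- rep(0, nm)
  for (j in which(usable)) {
    x <- M[, j]
    if (startsWith(colnames(M)[j], "cov")) x <- -x   # largest-to-smallest
    r <- rank(x, ties.method = "average")
    points <- points + (nm - r) / (nm - 1)
  }
  final <- rank(-points, ties.method = "average")
  out <- data.frame(model = model_names, M, point = points, final_rank = final,
                    check.names = FALSE, row.names = NULL)
  out[order(out$final_rank), , drop = FALSE]
}

#' Rank LSTM and baseline reports together
#'
#' Thin wrapper over [rank_models()] that produces the model-comparison
#' table layout: model name, the 12 submetrics, Point, final rank.
#'
#' @param reports List of `evaluation_report` objects.
#' @param path Optional CSV path to write the table to.
#' @return The ranking data frame (invisibly written to `path` if given).
#' @export
compare_models <- function(reports, path = NULL) {
  tab <- rank_models(reports)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
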