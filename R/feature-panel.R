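#' Daily feature panel
#'
#' The container the whole pipeline operates on: a patients x days x
#' features numeric array with an explicit missingness mask. Missing cells
#' are `NA` until imputation replaces them; every feature carries a
#' provenance tag (`sensor`, `symptom`, `deviation`, `date_index`,
#' `injected_probability`).
#'
#' @param values Numeric array \[n_patients, n_days, n_features\] with `NA`
#'   for missing cells; `dimnames` may name patients and features.
#' @param patients Character vector of patient ids (defaults to dimnames).
#' @param features Character vector of feature names (defaults to dimnames).
#' @param tags Character vector of provenance tags, one per feature.
#' @param lengths Integer vector: number of usable days per patient
#'   (defaults to the full day dimension). Rows past a patient's length are
#'   ignored by every downstream computation.
#' @return An object of class `feature_panel`.
#' @export
feature_panel <- function(values, patients = NULL, features = NULL,
                          tags = NULL, lengths = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (is.null(patients)) patients <- dimnames(values)[[1]]
  if (is.null(patients)) patients <- sprintf("p%02d", seq_len(d[1]))
  if (is.null(features)) features <- dimnames(values)[[3]]
  if (is.null(features)) features <- sprintf("f%03d", seq_len(d[3]))
  if (is.null(tags)) tags <- rep("sensor", d[3])
  if (is.null(lengths)) lengths <- rep(d[2], d[1])
  stopifnot(length(patients) == d[1], length(features) == d[3],
            length(tags) == d[3], length(lengths) == d[1])
  dimnames(values) <- list(patients, NULL, features)
  structure(list(values = values, patients = patients,
                 features = features, tags = unname(tags),
                 lengths = as.integer(lengths),
                 imputed = NULL, norm = NULL, log = NULL),
            class = "feature_panel")
}

#' @export
print.feature_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_panel> %d patients x %d days x %d features\n",
              d[1], d[2], d[3]))
  tab <- table(x$tags)
  cat("  tags:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing: %.1f%%%s\n", 100 * miss,
              if (!is.null(x$norm)) "  (normalized)" else ""))
  invisible(x)
}

#' @export
dim.feature_panel <- function(x) dim(x$values)

# cells past each patient's length, as a logical [patient, day] matrix
active_days <- function(panel) {
  d <- dim(panel$values)
  outer(seq_len(d[1]), seq_len(d[2]),
        function(i, j) j <= panel$lengths[i])
}

#' Read / write a daily feature table
#'
#' The CSV has one row per patient-day: columns `patient_id`, `day`, then
#' one numeric column per feature; empty cells are missing. Days absent from
#' the file are treated as fully missing up to each patient's maximum day.
#'
#' @param path CSV path.
#' @param horizon Day dimension of the resulting panel (default: maximum day
#'   present in the file).
#' @param tags Optional tag vector, one per feature column (default: columns
#'   named `symptom*` are tagged `symptom`, the rest `sensor`).
#' @return A [feature_panel()].
#' @export
read_feature_panel <- function(path, horizon = NULL, tags = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "day") %in% names(df))) {
    stop("feature CSV needs `patient_id` and `day` columns", call. = FALSE)
  }
  feats <- setdiff(names(df), c("patient_id", "day"))
  patients <- unique(as.character(df$patient_id))
  H <- if (is.null(horizon)) max(df$day) else as.integer(horizon)
  vals <- array(NA_real_, dim = c(length(patients), H, length(feats)),
                dimnames = list(patients, NULL, feats))
  pi <- match(as.character(df$patient_id), patients)
  for (j in seq_along(feats)) {
    vals[cbind(pi, df$day, j)] <- as.numeric(df[[feats[j]]])
  }
  if (is.null(tags)) {
    tags <- ifelse(grepl("^symptom", feats), "symptom", "sensor")
  }
  feature_panel(vals, patients = patients, features = feats, tags = tags)
}

#' @param panel A [feature_panel()].
#' @rdname read_feature_panel
#' @export
write_feature_panel <- function(panel, path) {
  d <- dim(panel$values)
  rows <- do.call(rbind, lapply(seq_len(d[1]), function(i) {
    days <- seq_len(panel$lengths[i])
    cbind(data.frame(patient_id = panel$patients[i], day = days),
          as.data.frame(matrix(panel$values[i, days, , drop = FALSE],
                               nrow = length(days),
                               dimnames = list(NULL, panel$features))))
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Feature manifest (kept/dropped features, tags, scaling)
#'
#' Writes a JSON manifest of the processing applied to a panel: per-feature
#' tags, the filter log (dropped features and reasons) and min-max scaling
#' parameters, so a processed panel can be audited or inverted.
#'
#' @param panel A processed [feature_panel()].
#' @param path JSON output path.
#' @export
write_feature_manifest <- function(panel, path) {
  jsonlite::write_json(
    list(features = panel$features, tags = panel$tags,
         dropped = panel$log, scaling = panel$norm),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
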