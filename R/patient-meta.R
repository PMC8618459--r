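#' Patient discharge metadata
#'
#' Bundles the administrative information known for one patient at (second)
#' discharge: whether and when they were readmitted within the follow-up
#' horizon, and their LACE and HOSPITAL readmission-risk scores.
#'
#' The LACE index (Length of stay, Acuity, Comorbidities, Emergency visits)
#' is an integer from 0 to 19; the HOSPITAL score (Hemoglobin, Oncology,
#' Sodium, Procedure, Index admission Type, Admissions, Length of stay) is an
#' integer from 0 to 15. Both are computed by hospitals at discharge; this
#' package consumes the integer scores, it does not derive them from EHR
#' fields.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param readmitted Logical; was the patient readmitted within the horizon?
#' @param readmission_day Integer day index (day 1 = first day after
#'   discharge) of the readmission, required iff `readmitted`.
#' @param second_discharge_day Integer day index of the discharge that ends
#'   the readmission stay, strictly greater than `readmission_day`; required
#'   iff `readmitted`.
#' @param lace Integer LACE score in 0..19.
#' @param hospital Integer HOSPITAL score in 0..15.
#' @return An object of class `patient_meta`.
#' @examples
#' patient_meta("p01", readmitted = FALSE, lace = 10, hospital = 6)
#' patient_meta("p02", readmitted = TRUE, readmission_day = 16,
#'              second_discharge_day = 21, lace = 10, hospital = 8)
#' @export
patient_meta <- function(patient_id, readmitted = FALSE,
                         readmission_day = NA_integer_,
                         second_discharge_day = NA_integer_,
                         lace = NA_integer_, hospital = NA_integer_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  readmitted <- isTRUE(readmitted)
  check_score <- function(x, name, lo, hi) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < lo || x > hi) {
      stop(sprintf("`%s` must be a single integer in [%d, %d], got %s",
                   name, lo, hi, deparse(x)), call. = FALSE)
    }
    as.integer(x)
  }
  lace <- check_score(lace, "lace", 0L, 19L)
  hospital <- check_score(hospital, "hospital", 0L, 15L)
  if (readmitted) {
    if (is.na(readmission_day) || is.na(second_discharge_day)) {
      stop("readmitted patients need `readmission_day` and `second_discharge_day`",
           call. = FALSE)
    }
    readmission_day <- as.integer(readmission_day)
    second_discharge_day <- as.integer(second_discharge_day)
    if (readmission_day < 2L) {
      stop("`readmission_day` must be >= 2", call. = FALSE)
    }
    if (second_discharge_day <= readmission_day) {
      stop("`second_discharge_day` must exceed `readmission_day`", call. = FALSE)
    }
  } else {
    if (!is.na(readmission_day) || !is.na(second_discharge_day)) {
      stop("non-readmitted patients must not carry readmission days", call. = FALSE)
    }
    readmission_day <- NA_integer_
    second_discharge_day <- NA_integer_
  }
  structure(
    list(patient_id = patient_id, readmitted = readmitted,
         readmission_day = readmission_day,
         second_discharge_day = second_discharge_day,
         lace = lace, hospital = hospital),
    class = "patient_meta"
  )
}

#' @export
print.patient_meta <- function(x, ...) {
  cat(sprintf("<patient_meta> %s  LACE=%d HOSPITAL=%d  %s\n",
              x$patient_id, x$lace, x$hospital,
              if (x$readmitted)
                sprintf("readmitted day %d, discharged day %d",
                        x$readmission_day, x$second_discharge_day)
              else "not readmitted"))
  invisible(x)
}

#' Read / write a patient metadata table
#'
#' The CSV has columns `patient_id`, `readmitted` (0/1 or logical),
#' `readmission_day`, `second_discharge_day` (empty for non-readmitted
#' patients), `lace`, `hospital`.
#'
#' @param path Path to a CSV file.
#' @return `read_patient_meta()` returns a named list of [patient_meta()]
#'   objects (names are patient ids).
#' @export
read_patient_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "readmitted", "readmission_day",
            "second_discharge_day", "lace", "hospital")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  metas <- lapply(seq_len(nrow(df)), function(i) {
    patient_meta(as.character(df$patient_id[i]),
                 readmitted = as.logical(df$readmitted[i]),
                 readmission_day = df$readmission_day[i],
                 second_discharge_day = df$second_discharge_day[i],
                 lace = df$lace[i], hospital = df$hospital[i])
  })
  names(metas) <- vapply(metas, `[[`, "", "patient_id")
  metas
}

#' @param metas Named list of [patient_meta()] objects.
#' @rdname read_patient_meta
#' @export
write_patient_meta <- function(metas, path) {
  df <- do.call(rbind, lapply(metas, function(m) {
    data.frame(patient_id = m$patient_id,
               readmitted = as.integer(m$readmitted),
               readmission_day = m$readmission_day,
               second_discharge_day = m$second_discharge_day,
               lace = m$lace, hospital = m$hospital)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
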