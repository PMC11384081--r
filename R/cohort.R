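#' Time-activity cohort container
#'
#' Validates and canonicalises per-patient time-activity observations. Times
#' are converted to minutes (the internal time base); activities are
#' fractions of the injected activity and must be strictly positive because
#' the residual model acts on log observations.
#'
#' @param data data.frame with columns \code{patient_id}, \code{time},
#'   \code{activity}.
#' @param time_unit unit of the \code{time} column: \code{"min"}, \code{"h"}
#'   or \code{"d"}.
#' @return A data.frame of class \code{"ta_cohort"} with columns
#'   \code{patient_id} (character), \code{time} (minutes, sorted within
#'   patient) and \code{activity}.
#' @examples
#' ta_cohort(data.frame(patient_id = "P1", time = c(1, 21, 164),
#'                      activity = c(0.04, 0.03, 0.01)), time_unit = "h")
#' @export
ta_cohort <- function(data, time_unit = c("min", "h", "d")) {
  time_unit <- match.arg(time_unit)
  need <- c("patient_id", "time", "activity")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(patient_id = as.character(data$patient_id),
                   time = as.numeric(data$time),
                   activity = as.numeric(data$activity),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(df$time) | !is.finite(df$activity))
  if (length(bad))
    stop("non-numeric or missing values in row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(df$activity <= 0)
  if (length(bad))
    stop("non-positive activity (log-residual model undefined) in row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(df$time < 0)
  if (length(bad))
    stop("negative time in row(s): ", paste(bad, collapse = ", "))
  df$time <- df$time * switch(time_unit, min = 1, h = 60, d = 1440)
  key <- paste(df$patient_id, signif(df$time, 12))
  if (anyDuplicated(key))
    stop("duplicate (patient, time) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df <- df[order(match(df$patient_id, unique(df$patient_id)), df$time), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ta_cohort", "data.frame")
  df
}

#' @export
print.ta_cohort <- function(x, ...) {
  ids <- unique(x$patient_id)
  cat(sprintf("Time-activity cohort: %d patients, %d observations\n",
              length(ids), nrow(x)))
  npts <- table(factor(x$patient_id, levels = ids))
  cat("Observations per patient:",
      paste(sprintf("%s=%d", names(npts), npts), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.ta_cohort <- function(object, ...) {
  ids <- unique(object$patient_id)
  cat(sprintf("%d patients, %d observations\n", length(ids), nrow(object)))
  cat(sprintf("time range: %.1f - %.1f min (%.2f - %.1f h)\n",
              min(object$time), max(object$time),
              min(object$time) / 60, max(object$time) / 60))
  cat(sprintf("activity range: %.3g - %.3g\n",
              min(object$activity), max(object$activity)))
  invisible(object)
}

# split into the per-patient list form used by the fitting engine
.cohort_split <- function(cohort) {
  ids <- unique(cohort$patient_id)
  lapply(stats::setNames(ids, ids), function(id) {
    sub <- cohort[cohort$patient_id == id, , drop = FALSE]
    list(id = id, time = sub$time, activity = sub$activity)
  })
}

#' Read a time-activity cohort from delimited text
#'
#' Expects a header with columns \code{patient_id}, \code{time},
#' \code{activity} (tab- or comma-separated, autodetected).
#'
#' @param path file path.
#' @param time_unit unit of the time column (\code{"min"}, \code{"h"},
#'   \code{"d"}).
#' @return A \code{\link{ta_cohort}}.
#' @export
read_cohort <- function(path, time_unit = c("min", "h", "d")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  ta_cohort(df, time_unit = time_unit)
}

#' Write a time-activity cohort as tab-delimited text
#'
#' Times are written in the requested unit (default minutes, the internal
#' base); \code{read_cohort} on the output restores the cohort.
#'
#' @param cohort a \code{\link{ta_cohort}}.
#' @param path output file path.
#' @param time_unit unit for the written time column.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, time_unit = c("min", "h", "d")) {
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(cohort, "ta_cohort"))
  out <- as.data.frame(cohort)
  out$time <- out$time / switch(time_unit, min = 1, h = 60, d = 1440)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
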