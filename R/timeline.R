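#' Exposure timelines
#'
#' An exposure timeline is, per patient, the union of half-open day intervals
#' \code{[start, end)} during which the patient is considered covered by
#' supply. Intervals are merged and sorted; a patient with no positive-length
#' coverage simply has no rows. Day offsets follow the cohort convention
#' (day 0 = window start).
#'
#' @param intervals data.frame with columns \code{patient_id}, \code{start},
#'   \code{end} (days, \code{end > start}).
#' @param patients character vector of all patients the timeline covers
#'   (including those with no intervals); defaults to the patients present.
#' @return object of class \code{see_timeline}.
#' @export
new_timeline <- function(intervals, patients = unique(intervals$patient_id)) {
  stopifnot(all(c("patient_id", "start", "end") %in% names(intervals)))
  intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]
  parts <- split(intervals[, c("start", "end")], intervals$patient_id)
  merged <- lapply(parts, merge_interval_df)
  out <- if (length(merged)) {
    data.frame(
      patient_id = rep(names(merged), vapply(merged, nrow, 1L)),
      do.call(rbind, merged),
      row.names = NULL
    )
  } else {
    data.frame(patient_id = character(), start = numeric(), end = numeric())
  }
  structure(
    list(intervals = out, patients = unique(as.character(patients))),
    class = "see_timeline"
  )
}

#' @export
print.see_timeline <- function(x, ...) {
  cat(sprintf("<see_timeline> %d interval(s) over %d patient(s)\n",
              nrow(x$intervals), length(x$patients)))
  invisible(x)
}

#' True exposure timeline from simulated fills
#'
#' Each fill covers \code{[fill day, fill day + true_duration_days)}; a
#' patient's exposure is the union of these intervals. No carry-over is
#' modelled: unused supply never extends a later interval beyond the union.
#'
#' @param fills data.frame with \code{patient_id}, \code{day},
#'   \code{true_duration_days} (all fills must carry a true duration), e.g.
#'   the \code{fills} element of a simulated cohort.
#' @return a \code{see_timeline}.
#' @export
compute_true_exposure <- function(fills) {
  if (inherits(fills, "see_cohort")) fills <- fills$fills
  if (any(is.na(fills$true_duration_days)))
    stopf("all fills must have true_duration_days")
  new_timeline(
    data.frame(
      patient_id = fills$patient_id,
      start = fills$day,
      end = fills$day + fills$true_duration_days
    ),
    patients = unique(fills$patient_id)
  )
}

#' Estimated exposure timeline from assigned durations
#'
#' Per patient, the union of \code{[fill day, end-of-supply day)} intervals
#' from an assigned-durations table, merged into disjoint sorted pieces.
#'
#' @param assigned table from [assign_durations()] or [rdd_durations()]
#'   (needs \code{patient_id}, \code{day}, \code{end_day}).
#' @return a \code{see_timeline}.
#' @export
build_exposure_timeline <- function(assigned) {
  new_timeline(
    data.frame(
      patient_id = assigned$patient_id,
      start = assigned$day,
      end = assigned$end_day
    ),
    patients = unique(assigned$patient_id)
  )
}

#' Point-in-time exposure query
#'
#' @param timeline a \code{see_timeline}.
#' @param patient_id,day parallel vectors of query points.
#' @return logical vector: is the patient covered at that day
#'   (half-open intervals, so a patient is not exposed at its end-of-supply
#'   day itself)?
#' @export
exposed_at <- function(timeline, patient_id, day) {
  stopifnot(inherits(timeline, "see_timeline"), length(patient_id) == length(day))
  parts <- split(timeline$intervals, timeline$intervals$patient_id)
  mapply(function(p, d) {
    iv <- parts[[p]]
    if (is.null(iv)) return(FALSE)
    any(iv$start <= d & d < iv$end)
  }, as.character(patient_id), day, USE.NAMES = FALSE)
}

#' Continuous multiple-interval measure of medication availability (CMA)
#'
#' Fraction of the observational window covered by the union of true
#' exposure intervals: coverage of \code{[window[1], window[2])} divided by
#' its length.
#'
#' @param fills fills with \code{day} and \code{true_duration_days} for one
#'   patient (or several; coverage is pooled over all rows' patient — pass a
#'   single patient for per-patient CMA).
#' @param window numeric length-2, day offsets \code{c(start, end)} with
#'   \code{end > start}.
#' @return fraction in \code{[0, 1]}.
#' @export
compute_cma <- function(fills, window) {
  if (inherits(fills, "see_cohort")) fills <- fills$fills
  if (length(window) != 2L || window[2] <= window[1]) stopf("empty window")
  if (nrow(fills) == 0L) return(0)
  if (any(is.na(fills$true_duration_days)))
    stopf("all fills must have true_duration_days")
  iv <- merge_interval_df(data.frame(
    start = fills$day, end = fills$day + fills$true_duration_days))
  interval_coverage(iv, window[1], window[2]) / (window[2] - window[1])
}
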