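#' Construct a prescription-fill cohort
#'
#' A cohort holds the dispensing history of one drug: one row per fill
#' (patient identifier, calendar fill date, drug code, optional dispensed
#' quantity, optional simulated true duration) together with an observational
#' window. Internally all arithmetic is done on integer day offsets with
#' day 0 at \code{window_start}; calendar dates appear only at I/O boundaries.
#'
#' @param fills data.frame with columns \code{patient_id}, \code{fill_date}
#'   (\code{Date}), \code{drug_code}, and optionally \code{quantity} and
#'   \code{true_duration_days}.
#' @param window_start,window_end \code{Date} bounds of the observational
#'   window (\code{window_start < window_end}).
#' @return An object of class \code{see_cohort}: a list with elements
#'   \code{fills} (sorted by patient and date, with an integer \code{day}
#'   offset column) and the two window dates.
#' @export
new_cohort <- function(fills, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end) || window_start >= window_end)
    stopf("window_start must precede window_end")
  required <- c("patient_id", "fill_date", "drug_code")
  missing_cols <- setdiff(required, names(fills))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  fills$patient_id <- as.character(fills$patient_id)
  fills$fill_date <- as.Date(fills$fill_date)
  if (!"quantity" %in% names(fills)) fills$quantity <- NA_integer_
  if (!"true_duration_days" %in% names(fills)) fills$true_duration_days <- NA_integer_
  qty <- fills$quantity[!is.na(fills$quantity)]
  if (any(qty < 1)) stopf("quantity must be >= 1 when present")
  td <- fills$true_duration_days[!is.na(fills$true_duration_days)]
  if (any(td < 1)) stopf("true_duration_days must be >= 1 when present")
  o <- order(fills$patient_id, fills$fill_date)
  fills <- fills[o, , drop = FALSE]
  fills$day <- as.integer(fills$fill_date - window_start)
  rownames(fills) <- NULL
  structure(
    list(fills = fills, window_start = window_start, window_end = window_end),
    class = "see_cohort"
  )
}

#' @export
print.see_cohort <- function(x, ...) {
  cat(sprintf(
    "<see_cohort> %d fills, %d patients, window %s .. %s (%d days)\n",
    nrow(x$fills), length(unique(x$fills$patient_id)),
    format(x$window_start), format(x$window_end),
    as.integer(x$window_end - x$window_start)
  ))
  invisible(x)
}

#' Number of days in a cohort's observational window
#' @param cohort a \code{see_cohort}.
#' @return integer day count (\code{window_end - window_start}).
#' @export
window_days <- function(cohort) {
  as.integer(cohort$window_end - cohort$window_start)
}

#' Read prescription fills from delimited text
#'
#' Expects a UTF-8 comma-delimited file with a header containing at least
#' \code{patient_id}, \code{fill_date} and \code{drug_code};
#' \code{quantity} and \code{true_duration_days} are picked up when present.
#' Rows are sorted by (patient, date) on read.
#'
#' @param path file to read.
#' @param date_format \code{strptime} format for \code{fill_date}
#'   (default ISO-8601; register exports may override).
#' @param window_start,window_end optional window override; defaults to the
#'   range of the observed fill dates.
#' @return a \code{see_cohort}.
#' @export
read_fills <- function(path, date_format = "%Y-%m-%d",
                       window_start = NULL, window_end = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "fill_date", "drug_code")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  parsed <- as.Date(as.character(raw$fill_date), format = date_format)
  bad <- which(is.na(parsed))
  if (length(bad))
    stopf("unparseable fill_date on row %d: '%s'", bad[1L], raw$fill_date[bad[1L]])
  raw$fill_date <- parsed
  new_cohort(
    raw,
    window_start %||% min(parsed),
    window_end %||% max(parsed)
  )
}

#' Validate a cohort and enforce its invariants
#'
#' Drops fills outside the observational window (with a message giving the
#' count) and collapses duplicate (patient, date) rows into one fill, summing
#' quantities when present. Same-day duplicates would otherwise create
#' zero-day refill gaps that distort the gap ECDF. Idempotent.
#'
#' @param cohort a \code{see_cohort}.
#' @return the validated \code{see_cohort}.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "see_cohort"))
  f <- cohort$fills
  inside <- f$fill_date >= cohort$window_start & f$fill_date <= cohort$window_end
  if (any(!inside)) {
    message(sprintf("validate_cohort: dropped %d fill(s) outside the window",
                    sum(!inside)))
    f <- f[inside, , drop = FALSE]
  }
  if (nrow(f) == 0L) stopf("no fills remain inside the observational window")
  key <- paste(f$patient_id, f$fill_date)
  if (anyDuplicated(key)) {
    qty <- tapply(f$quantity, key, function(q) {
      if (all(is.na(q))) NA_integer_ else as.integer(sum(q, na.rm = TRUE))
    })
    first <- !duplicated(key)
    collapsed <- f[first, , drop = FALSE]
    collapsed$quantity <- as.integer(qty[paste(collapsed$patient_id,
                                               collapsed$fill_date)])
    f <- collapsed
  }
  new_cohort(f, cohort$window_start, cohort$window_end)
}

.duration_cols <- c("patient_id", "fill_date", "drug_code", "gap_days",
                    "cluster_id", "duration_days", "end_of_supply")

#' Write assigned durations to delimited text
#'
#' Writes one row per fill with ISO-8601 dates and a stable column order:
#' \code{patient_id, fill_date, drug_code, gap_days, cluster_id,
#' duration_days, end_of_supply}. \code{gap_days} is empty for each patient's
#' last fill.
#'
#' @param assigned table as returned by [assign_durations()] or
#'   [rdd_durations()].
#' @param path output file.
#' @export
write_durations <- function(assigned, path) {
  cols <- intersect(.duration_cols, names(assigned))
  need <- setdiff(c("patient_id", "fill_date", "duration_days", "end_of_supply"),
                  cols)
  if (length(need))
    stopf("assigned table lacks column(s): %s", paste(need, collapse = ", "))
  out <- assigned[, cols, drop = FALSE]
  out$fill_date <- format(as.Date(out$fill_date), "%Y-%m-%d")
  out$end_of_supply <- format(as.Date(out$end_of_supply), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a durations table written by [write_durations()]
#' @param path file to read.
#' @return data.frame with typed columns (dates as \code{Date}).
#' @export
read_durations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$patient_id <- as.character(x$patient_id)
  x$fill_date <- as.Date(x$fill_date)
  if ("end_of_supply" %in% names(x)) x$end_of_supply <- as.Date(x$end_of_supply)
  x
}
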