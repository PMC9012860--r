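#' Researcher-defined durations: one dispensed unit per day
#'
#' The fixed-assumption comparator: each fill's duration equals its dispensed
#' quantity under a consumption of one unit per day, so the end of supply is
#' the fill date plus the quantity. Row-local: unlike the data-driven
#' estimator, no other patient's data enters the computation. The output
#' schema matches [assign_durations()] so downstream evaluation is
#' interchangeable (\code{cluster_id} is NA throughout).
#'
#' @param cohort a validated \code{see_cohort} in which every fill has a
#'   \code{quantity}.
#' @return data.frame with the [assign_durations()] columns.
#' @export
rdd_durations <- function(cohort) {
  f <- cohort$fills
  bad <- which(is.na(f$quantity))
  if (length(bad))
    stopf("missing quantity on fill %d (patient %s, %s)",
          bad[1L], f$patient_id[bad[1L]], format(f$fill_date[bad[1L]]))
  n <- nrow(f)
  gap_days <- rep(NA_integer_, n)
  if (n > 1L) {
    same <- f$patient_id[-1L] == f$patient_id[-n]
    idx <- which(same)
    gap_days[idx] <- as.integer(f$day[idx + 1L] - f$day[idx])
  }
  end_day <- f$day + f$quantity
  data.frame(
    patient_id = f$patient_id,
    fill_date = f$fill_date,
    drug_code = f$drug_code,
    day = f$day,
    gap_days = gap_days,
    cluster_id = NA_integer_,
    duration_days = as.numeric(f$quantity),
    end_day = as.integer(end_day),
    end_of_supply = cohort$window_start + end_day
  )
}
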