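#' Draw one uniform random evaluation date per patient
#'
#' Dates are uniform over the observational window (inclusive of both
#' endpoints, at daily resolution) and deterministic given the seed.
#'
#' @param cohort a \code{see_cohort}.
#' @param seed integer seed.
#' @return data.frame \code{patient_id}, \code{day}, \code{date}.
#' @export
draw_random_dates <- function(cohort, seed) {
  set.seed(seed)
  ids <- sort(unique(cohort$fills$patient_id))
  w <- window_days(cohort)
  day <- sample.int(w + 1L, length(ids), replace = TRUE) - 1L
  data.frame(patient_id = ids, day = day, date = cohort$window_start + day)
}

#' Classify patients at their random dates
#'
#' Each patient contributes one confusion-matrix cell: true positive if
#' truly exposed and estimated exposed at the patient's date, false positive
#' if not truly exposed but estimated exposed, false negative if truly
#' exposed but estimated unexposed, true negative if neither.
#'
#' @param true_timeline,est_timeline \code{see_timeline}s covering every
#'   evaluated patient.
#' @param dates data.frame from [draw_random_dates()].
#' @return list with \code{matrix} (named counts \code{tp, fp, fn, tn}) and
#'   \code{by_patient} (per-patient truth, estimate and category).
#' @export
classify_random_dates <- function(true_timeline, est_timeline, dates) {
  missing_true <- setdiff(dates$patient_id, true_timeline$patients)
  missing_est <- setdiff(dates$patient_id, est_timeline$patients)
  if (length(missing_true) || length(missing_est))
    stopf("patient missing from a timeline: %s",
          paste(utils::head(c(missing_true, missing_est), 3L), collapse = ", "))
  truth <- exposed_at(true_timeline, dates$patient_id, dates$day)
  est <- exposed_at(est_timeline, dates$patient_id, dates$day)
  category <- ifelse(truth & est, "TP",
              ifelse(!truth & est, "FP",
              ifelse(truth & !est, "FN", "TN")))
  m <- c(tp = sum(truth & est), fp = sum(!truth & est),
         fn = sum(truth & !est), tn = sum(!truth & !est))
  list(
    matrix = m,
    by_patient = data.frame(patient_id = dates$patient_id, day = dates$day,
                            truth = truth, estimated = est,
                            category = category)
  )
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' Computes the ten metrics of the random-date evaluation: accuracy,
#' sensitivity (= recall), specificity, PPV (= precision), NPV, balanced
#' accuracy, Cohen's kappa (marginal-product chance agreement), and F1.
#' Ratios with a zero denominator are reported as \code{NaN}, never coerced
#' to 0, so degenerate runs stay visible.
#'
#' @param m named counts \code{c(tp=, fp=, fn=, tn=)} (or the list returned
#'   by [classify_random_dates()]).
#' @return named list of the ten metrics (fractions in \code{[0, 1]}) plus
#'   the matrix itself.
#' @export
compute_metrics <- function(m) {
  if (is.list(m) && !is.null(m$matrix)) m <- m$matrix
  tp <- m[["tp"]]; fp <- m[["fp"]]; fn <- m[["fn"]]; tn <- m[["tn"]]
  n <- tp + fp + fn + tn
  if (n == 0) stopf("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sensitivity <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NaN else (po - pe) / (1 - pe)
  f1 <- if (is.nan(ppv) || is.nan(sensitivity) || (ppv + sensitivity) == 0) NaN
        else 2 * ppv * sensitivity / (ppv + sensitivity)
  list(
    matrix = c(tp = tp, fp = fp, fn = fn, tn = tn),
    accuracy = po,
    sensitivity = sensitivity,
    specificity = specificity,
    ppv = ppv,
    npv = npv,
    balanced_accuracy = (sensitivity + specificity) / 2,
    kappa = kappa,
    f1 = f1,
    recall = sensitivity,
    precision = ppv
  )
}

#' Misclassification of duration in days
#'
#' For every fill, the absolute difference between the simulated true
#' duration and the assigned duration; medians and interquartile ranges are
#' summarized per random-date category (TP/FP/FN/TN), pooled over TP, TN
#' and FN, and over all fills. Fills are matched 1:1 by (patient, fill day).
#'
#' @param cohort simulated \code{see_cohort} (fills carry
#'   \code{true_duration_days}).
#' @param assigned table from [assign_durations()] or [rdd_durations()].
#' @param classification result of [classify_random_dates()] supplying each
#'   patient's category.
#' @return list with \code{per_fill} (one row per fill) and \code{summary}
#'   (n, median, q1, q3 per category and pooled).
#' @export
misclassification_days <- function(cohort, assigned, classification) {
  truth <- cohort$fills
  key_t <- paste(truth$patient_id, truth$day)
  key_a <- paste(assigned$patient_id, assigned$day)
  pos <- match(key_t, key_a)
  if (anyNA(pos) || length(key_t) != length(key_a))
    stopf("fills are not matched 1:1 between truth and assignment")
  if (any(is.na(truth$true_duration_days)))
    stopf("true_duration_days required on every fill")
  cat_by_patient <- stats::setNames(classification$by_patient$category,
                                    classification$by_patient$patient_id)
  per_fill <- data.frame(
    patient_id = truth$patient_id,
    fill_date = truth$fill_date,
    day = truth$day,
    true_duration_days = truth$true_duration_days,
    assigned_duration_days = assigned$duration_days[pos],
    category = unname(cat_by_patient[truth$patient_id])
  )
  per_fill$abs_diff_days <-
    abs(per_fill$true_duration_days - per_fill$assigned_duration_days)

  summarize <- function(d) {
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(n = length(d), q1 = q[1], median = q[2], q3 = q[3])
  }
  pieces <- c(
    lapply(split(per_fill$abs_diff_days, per_fill$category), summarize),
    list(pooled_tp_tn_fn = summarize(
           per_fill$abs_diff_days[per_fill$category %in% c("TP", "TN", "FN")]),
         all = summarize(per_fill$abs_diff_days))
  )
  summary <- data.frame(
    category = names(pieces),
    do.call(rbind, pieces),
    row.names = NULL
  )
  list(per_fill = per_fill, summary = summary)
}

#' Balanced-subsample sensitivity analysis
#'
#' The random-date classes are heavily unbalanced (most patients are true
#' positives). True-positive patients are down-sampled uniformly at random
#' to the size of the largest remaining class, and the retained population
#' is re-evaluated at freshly drawn random dates. Re-evaluation (rather than
#' just shrinking the TP count) is what lets composition-sensitive metrics
#' such as NPV respond: removing predominantly well-covered patients shifts
#' the estimated-negative pool toward the truly unexposed. If there is no
#' TP excess the original report is returned with a message.
#'
#' @param cohort the evaluated \code{see_cohort} (for the window).
#' @param true_timeline,est_timeline the timelines used in the original
#'   classification.
#' @param classification result of [classify_random_dates()].
#' @param seed integer seed for both the subsample and the new dates.
#' @return list: \code{metrics} (as [compute_metrics()]),
#'   \code{classification} of the balanced set, and \code{kept_patients}.
#' @export
balanced_subsample <- function(cohort, true_timeline, est_timeline,
                               classification, seed) {
  bp <- classification$by_patient
  counts <- classification$matrix
  target <- max(counts[c("fp", "fn", "tn")])
  if (counts[["tp"]] <= target) {
    message("balanced_subsample: no true-positive excess; returning original report")
    return(list(metrics = compute_metrics(classification),
                classification = classification,
                kept_patients = bp$patient_id))
  }
  set.seed(seed)
  tp_ids <- bp$patient_id[bp$category == "TP"]
  keep_tp <- sample(tp_ids, target)
  kept <- c(bp$patient_id[bp$category != "TP"], keep_tp)
  sub <- new_cohort(cohort$fills[cohort$fills$patient_id %in% kept, , drop = FALSE],
                    cohort$window_start, cohort$window_end)
  dates <- draw_random_dates(sub, seed + 1L)
  cls <- classify_random_dates(true_timeline, est_timeline, dates)
  list(metrics = compute_metrics(cls), classification = cls,
       kept_patients = sort(kept))
}

#' Sensitivity at externally supplied truth-event dates
#'
#' An event (e.g. a day on which drug exposure was directly observed) counts
#' as detected when any estimated exposure interval intersects
#' \code{[event - tolerance, event + tolerance]} days. The default tolerance
#' of 0 demands coverage on the event day itself; a drug-half-life-based
#' tolerance can be supplied by the caller.
#'
#' @param est_timeline a \code{see_timeline}.
#' @param events data.frame with \code{patient_id} and \code{day} (or
#'   \code{event_date} plus a timeline anchored elsewhere — day offsets are
#'   required here).
#' @param tolerance_days nonnegative integer.
#' @return fraction of events detected, in \code{[0, 1]}.
#' @export
sensitivity_at_event_dates <- function(est_timeline, events, tolerance_days = 0L) {
  if (nrow(events) == 0L) stopf("empty event list")
  if (tolerance_days < 0L) stopf("tolerance_days must be nonnegative")
  missing <- setdiff(events$patient_id, est_timeline$patients)
  if (length(missing))
    stopf("patient missing from timeline: %s", missing[1L])
  parts <- split(est_timeline$intervals, est_timeline$intervals$patient_id)
  detected <- mapply(function(p, d) {
    iv <- parts[[p]]
    if (is.null(iv)) return(FALSE)
    any(iv$start <= d + tolerance_days & iv$end > d - tolerance_days)
  }, as.character(events$patient_id), events$day, USE.NAMES = FALSE)
  mean(detected)
}

#' Sample truth events from truly exposed days
#'
#' Draws, for each patient with any true exposure, one event day uniformly
#' from that patient's truly exposed days inside the window. Mirrors a
#' biomarker-style external truth source: events exist only where exposure
#' really occurred.
#'
#' @param true_timeline a \code{see_timeline} of true exposure.
#' @param window_days window length (events are restricted to
#'   \code{[0, window_days]}).
#' @param seed integer seed.
#' @return data.frame \code{patient_id}, \code{day}.
#' @export
draw_events_from_exposure <- function(true_timeline, window_days, seed) {
  set.seed(seed)
  parts <- split(true_timeline$intervals, true_timeline$intervals$patient_id)
  out <- lapply(names(parts), function(p) {
    iv <- parts[[p]]
    days <- unlist(mapply(function(s, e) {
      lo <- max(s, 0); hi <- min(e - 1, window_days)
      if (hi < lo) integer(0) else seq(lo, hi)
    }, iv$start, iv$end, SIMPLIFY = FALSE))
    if (!length(days)) return(NULL)
    data.frame(patient_id = p,
               day = if (length(days) == 1L) days else sample(days, 1L))
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
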