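#' SEE configuration
#'
#' Tuning parameters of the Sessa Empirical Estimator: the fraction of the
#' refill-gap ECDF to retain (the remainder holds the artificially long gaps
#' of stoppers and re-starters), the k-means search range and restart count,
#' and the RNG seed that drives the one-random-pair-per-patient draw and the
#' k-means initializations.
#'
#' @param ecdf_retention fraction of the gap ECDF retained, in (0, 1].
#' @param k_min,k_max inclusive bounds of the cluster-count search
#'   (silhouette analysis needs k_min >= 2; k_max is additionally capped at
#'   one below the number of distinct sampled gaps).
#' @param n_restarts random k-means initializations per K; the best
#'   within-cluster sum of squares is kept.
#' @param seed integer seed.
#' @return list of class \code{see_config}.
#' @export
see_config <- function(ecdf_retention = 0.8, k_min = 2L, k_max = 10L,
                       n_restarts = 50L, seed = 42L) {
  if (!(ecdf_retention > 0 && ecdf_retention <= 1))
    stopf("ecdf_retention must lie in (0, 1]")
  if (k_min < 2L || k_min > k_max) stopf("need 2 <= k_min <= k_max")
  structure(
    list(ecdf_retention = ecdf_retention, k_min = as.integer(k_min),
         k_max = as.integer(k_max), n_restarts = as.integer(n_restarts),
         seed = as.integer(seed)),
    class = "see_config"
  )
}

degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("see_degenerate_error", "error", "condition")))
}

#' Refill gaps between consecutive fills
#'
#' One row per consecutive same-patient fill pair: the temporal distance in
#' days between the two fill dates. Patients with a single fill contribute
#' nothing. Same-day duplicates must have been merged upstream
#' ([validate_cohort()]), so every gap is >= 1 day.
#'
#' @param cohort a validated \code{see_cohort}.
#' @return data.frame \code{patient_id}, \code{fill_index} (ordinal of the
#'   earlier fill within the patient), \code{gap_days}.
#' @export
compute_refill_gaps <- function(cohort) {
  f <- cohort$fills
  n <- nrow(f)
  if (n < 2L)
    return(data.frame(patient_id = character(), fill_index = integer(),
                      gap_days = integer()))
  same <- f$patient_id[-1L] == f$patient_id[-n]
  idx <- which(same)
  within_idx <- stats::ave(seq_len(n), f$patient_id, FUN = seq_along)
  data.frame(
    patient_id = f$patient_id[idx],
    fill_index = within_idx[idx],
    gap_days = as.integer(f$day[idx + 1L] - f$day[idx])
  )
}

#' Trim the upper tail of the gap ECDF
#'
#' The cutoff is the smallest observed gap value whose empirical cumulative
#' probability reaches the retention fraction (ties included), so at least
#' that fraction of gaps is retained and only the largest gaps are removed.
#'
#' @param gaps data.frame from [compute_refill_gaps()].
#' @param retention fraction in (0, 1].
#' @return list with \code{retained} (subset of \code{gaps}) and
#'   \code{cutoff_days}.
#' @export
trim_ecdf <- function(gaps, retention = 0.8) {
  n <- nrow(gaps)
  if (n == 0L) stopf("no refill gaps to trim")
  sorted <- sort(gaps$gap_days)
  cutoff <- sorted[ceiling(retention * n)]
  list(retained = gaps[gaps$gap_days <= cutoff, , drop = FALSE],
       cutoff_days = cutoff)
}

#' One random retained gap per patient
#'
#' Selecting a single random consecutive pair per patient removes the
#' over-representation of patients who refill often (small amounts
#' dispensed) relative to those who refill rarely. Patients whose every gap
#' exceeded the ECDF cutoff are simply absent.
#'
#' @param gaps retained gaps (data.frame with \code{patient_id},
#'   \code{gap_days}).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return data.frame with exactly one row per represented patient.
#' @export
sample_random_pairs <- function(gaps, seed) {
  if (nrow(gaps) == 0L) stopf("no retained gaps to sample from")
  set.seed(seed)
  ids <- sort(unique(gaps$patient_id))
  rows <- vapply(ids, function(p) {
    cand <- which(gaps$patient_id == p)
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, integer(1))
  out <- gaps[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize gap values
#'
#' Centers by the mean and scales by the sample standard deviation
#' (n - 1 denominator); the mean and sd are returned so model predictions can
#' map new gaps onto the same scale.
#'
#' @param x numeric vector, length >= 2.
#' @return list \code{z}, \code{mean}, \code{sd}.
#' @export
standardize <- function(x) {
  if (length(x) < 2L) stopf("need at least 2 values to standardize")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) degenerate_error("zero variance: standardization undefined")
  list(z = (x - m) / s, mean = m, sd = s)
}

# best-inertia k-means at a fixed K with distinct initial centers per restart
.kmeans_best <- function(z, k, n_restarts) {
  ux <- unique(z)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    centers0 <- matrix(if (length(ux) == k) ux else sample(ux, k))
    km <- suppressWarnings(stats::kmeans(matrix(z), centers = centers0,
                                         iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Select the number of clusters by silhouette analysis
#'
#' For each K in the search range, k-means (squared-Euclidean, best of
#' \code{n_restarts} random initializations) partitions the standardized
#' gaps, and the average silhouette width of the partition is computed. The
#' K with the highest average width wins; ties break toward the smaller K.
#' If fewer than \code{k_min + 1} distinct values are available but at least
#' two are, K is fixed at the number of distinct values (one cluster per
#' value); a single distinct value is a degenerate input.
#'
#' @param z standardized gaps.
#' @param k_min,k_max search bounds (k_max capped at distinct values - 1).
#' @param n_restarts restarts per K.
#' @param seed integer seed for the initializations.
#' @return list \code{k_selected}, \code{silhouette_by_k} (named numeric),
#'   \code{cluster} (assignments relabelled so cluster 1 has the smallest
#'   center), \code{centers} (ascending, standardized scale).
#' @export
select_k_silhouette <- function(z, k_min = 2L, k_max = 10L,
                                n_restarts = 50L, seed = 42L) {
  n_distinct <- length(unique(z))
  if (n_distinct < 2L)
    degenerate_error("fewer than 2 distinct values: clustering undefined")
  ks <- if (n_distinct - 1L >= k_min) seq(k_min, min(k_max, n_distinct - 1L))
        else n_distinct
  d <- stats::dist(z)
  sil <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(seed + ks[i])
    km <- .kmeans_best(z, ks[i], n_restarts)
    fits[[i]] <- km
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  names(sil) <- ks
  best <- which.max(sil)  # first maximum = smaller K on ties
  km <- fits[[best]]
  relabel <- order(km$centers[, 1L])
  new_label <- match(seq_along(relabel), relabel)
  list(
    k_selected = ks[best],
    silhouette_by_k = sil,
    cluster = new_label[km$cluster],
    centers = as.numeric(km$centers[relabel, 1L])
  )
}

#' Fit the Sessa Empirical Estimator
#'
#' Runs the five-step pipeline on a cohort: (1) compute all consecutive-fill
#' gaps and retain the lower \code{ecdf_retention} of their ECDF; (2) draw
#' one random retained gap per patient; (3) standardize and cluster with
#' k-means, selecting K by average silhouette width; (4) take the empirical
#' median of each cluster's gaps (original day scale) as that cluster's
#' prescription duration. Step (5), the end of supply per fill, is applied
#' by [assign_durations()]. If the sampled gaps are all identical the model
#' degenerates to a single cluster whose duration is that common value.
#'
#' @param cohort a validated \code{see_cohort} with >= 2 patients having
#'   >= 2 fills.
#' @param config a [see_config()].
#' @return object of class \code{see_model}.
#' @export
fit_see <- function(cohort, config = see_config()) {
  stopifnot(inherits(config, "see_config"))
  gaps <- compute_refill_gaps(cohort)
  if (nrow(gaps) == 0L) stopf("no patient has >= 2 fills; cannot fit")
  trimmed <- trim_ecdf(gaps, config$ecdf_retention)
  sampled <- sample_random_pairs(trimmed$retained, config$seed)
  x <- sampled$gap_days

  degenerate <- length(unique(x)) < 2L
  if (degenerate) {
    model <- list(
      retention_cutoff_days = trimmed$cutoff_days,
      standardization_mean = mean(x), standardization_sd = NA_real_,
      k_selected = 1L, centers_std = 0,
      median_duration_days = round(stats::median(x), 2),
      silhouette_by_k = stats::setNames(numeric(0), character(0)),
      sampled_gaps = sampled, cluster = rep(1L, length(x)),
      config = config
    )
    return(structure(model, class = "see_model"))
  }

  st <- standardize(x)
  sel <- select_k_silhouette(st$z, config$k_min, config$k_max,
                             config$n_restarts, config$seed)
  medians <- vapply(seq_len(sel$k_selected), function(k) {
    round(stats::median(x[sel$cluster == k]), 2)
  }, numeric(1))
  structure(
    list(
      retention_cutoff_days = trimmed$cutoff_days,
      standardization_mean = st$mean, standardization_sd = st$sd,
      k_selected = sel$k_selected, centers_std = sel$centers,
      median_duration_days = medians,
      silhouette_by_k = sel$silhouette_by_k,
      sampled_gaps = sampled, cluster = sel$cluster,
      config = config
    ),
    class = "see_model"
  )
}

#' @export
print.see_model <- function(x, ...) {
  cat(sprintf("<see_model> K = %d cluster(s)\n", x$k_selected))
  cat(sprintf("  ECDF cutoff: %s days; standardization mean %.2f, sd %s\n",
              format(x$retention_cutoff_days), x$standardization_mean,
              ifelse(is.na(x$standardization_sd), "-",
                     sprintf("%.2f", x$standardization_sd))))
  cat("  cluster median durations (days):",
      paste(format(x$median_duration_days), collapse = ", "), "\n")
  if (length(x$silhouette_by_k)) {
    cat("  avg silhouette by K:",
        paste(sprintf("%s=%.3f", names(x$silhouette_by_k), x$silhouette_by_k),
              collapse = "  "), "\n")
  }
  invisible(x)
}

# nearest standardized center; ties break toward the smaller center
.nearest_cluster <- function(z, centers) {
  dmat <- abs(outer(z, centers, "-"))
  max.col(-dmat, ties.method = "first")
}

#' Assign durations and ends of supply to every fill
#'
#' Every fill followed by another same-patient fill has its gap standardized
#' with the model's mean/sd and assigned to the nearest cluster center; its
#' duration is that cluster's median (gaps above the ECDF cutoff still get a
#' nearest-center assignment, effectively capping their duration at the
#' largest cluster median). A patient's last fill, which has no following
#' gap, inherits the cluster median of that patient's most recent assigned
#' fill; a patient with no assigned gap at all gets the overall median of
#' the cluster medians, rounded to the nearest day. The end of supply is the
#' fill date plus the assigned duration (rounded to whole days, half away
#' from zero).
#'
#' @param cohort a validated \code{see_cohort}.
#' @param model a fitted [fit_see()] model.
#' @return data.frame with one row per fill: \code{patient_id},
#'   \code{fill_date}, \code{drug_code}, \code{day}, \code{gap_days} (NA on
#'   last fills), \code{cluster_id} (NA on inherited rows),
#'   \code{duration_days}, \code{end_day}, \code{end_of_supply}.
#' @export
assign_durations <- function(cohort, model) {
  if (!inherits(model, "see_model")) stopf("model must be a fitted see_model")
  f <- cohort$fills
  n <- nrow(f)
  gap_days <- rep(NA_integer_, n)
  if (n > 1L) {
    same <- f$patient_id[-1L] == f$patient_id[-n]
    idx <- which(same)
    gap_days[idx] <- as.integer(f$day[idx + 1L] - f$day[idx])
  }

  cluster_id <- rep(NA_integer_, n)
  duration <- rep(NA_real_, n)
  has_gap <- !is.na(gap_days)
  if (model$k_selected == 1L) {
    cluster_id[has_gap] <- 1L
    duration[has_gap] <- model$median_duration_days[1L]
  } else {
    z <- (gap_days[has_gap] - model$standardization_mean) / model$standardization_sd
    cl <- .nearest_cluster(z, model$centers_std)
    cluster_id[has_gap] <- cl
    duration[has_gap] <- model$median_duration_days[cl]
  }

  global_fallback <- round_half_up(stats::median(model$median_duration_days))
  for (i in which(!has_gap)) {
    if (i > 1L && f$patient_id[i - 1L] == f$patient_id[i] && !is.na(duration[i - 1L])) {
      duration[i] <- duration[i - 1L]   # last fill inherits the previous cluster median
    } else {
      duration[i] <- global_fallback    # single-fill patient
    }
  }

  end_day <- f$day + round_half_up(duration)
  data.frame(
    patient_id = f$patient_id,
    fill_date = f$fill_date,
    drug_code = f$drug_code,
    day = f$day,
    gap_days = gap_days,
    cluster_id = cluster_id,
    duration_days = duration,
    end_day = as.integer(end_day),
    end_of_supply = cohort$window_start + end_day
  )
}
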