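# Independent oracles used to freeze expected values. These deliberately do
# not reuse any code path from the package (hand-rolled silhouette instead of
# cluster::silhouette, exhaustive enumeration instead of kmeans).

# ECDF trim by direct definition: sort, take the smallest value whose
# cumulative count / n reaches the retention fraction.
oracle_trim_cutoff <- function(gaps, retention) {
  s <- sort(gaps)
  n <- length(s)
  for (g in unique(s)) if (sum(s <= g) / n >= retention) return(g)
  s[n]
}

# Average silhouette width of a labelled partition, by the textbook formula
# (s = 0 for points in singleton clusters).
oracle_avg_silhouette <- function(x, labels) {
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Exhaustive K selection for 1-D data: optimal k-means clusters are
# contiguous in sorted order, so for each K enumerate all contiguous
# partitions (compositions), take the minimum within-cluster sum of squares,
# score it by average silhouette, and return the K with the highest score
# (ties toward smaller K).
oracle_select_k <- function(x, k_min = 2L, k_max = 10L) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  ks <- seq(k_min, min(k_max, length(unique(x)) - 1L))
  best_sil <- -Inf
  best_k <- NA_integer_
  sil_by_k <- stats::setNames(numeric(length(ks)), ks)
  labels_by_k <- list()
  for (k in ks) {
    cuts <- utils::combn(n - 1L, k - 1L)
    best_wss <- Inf
    best_lab <- NULL
    for (j in seq_len(ncol(cuts))) {
      bounds <- c(0L, cuts[, j], n)
      lab <- rep(seq_len(k), diff(bounds))
      wss <- sum(vapply(seq_len(k), function(cl) {
        v <- xs[lab == cl]; sum((v - mean(v))^2)
      }, numeric(1)))
      if (wss < best_wss) { best_wss <- wss; best_lab <- lab }
    }
    sil <- oracle_avg_silhouette(xs, best_lab)
    sil_by_k[as.character(k)] <- sil
    labels_by_k[[as.character(k)]] <- best_lab
    if (sil > best_sil + 1e-12) { best_sil <- sil; best_k <- k }
  }
  lab_sorted <- labels_by_k[[as.character(best_k)]]
  labels <- integer(n)
  labels[o] <- lab_sorted
  list(k_selected = best_k, silhouette_by_k = sil_by_k, cluster = labels)
}

# Day-by-day CMA: walk every day of the window and test membership in some
# [fill, fill + duration) interval.
oracle_cma <- function(day, dur, window) {
  days <- seq(window[1], window[2] - 1)
  covered <- vapply(days, function(d) any(day <= d & d < day + dur), logical(1))
  mean(covered)
}

# Classification metrics tallied from individual-level labels.
oracle_metrics <- function(truth, est) {
  list(
    accuracy = mean(truth == est),
    sensitivity = mean(est[truth]),
    specificity = mean(!est[!truth]),
    ppv = mean(truth[est]),
    npv = mean(!truth[!est])
  )
}

# Small literal cohort from day offsets.
make_cohort <- function(patient_id, day, window_days = NULL,
                        quantity = NULL, true_duration_days = NULL,
                        origin = as.Date("2010-01-01")) {
  w <- window_days %||% max(day)
  df <- data.frame(
    patient_id = patient_id,
    fill_date = origin + day,
    drug_code = "X01"
  )
  if (!is.null(quantity)) df$quantity <- quantity
  if (!is.null(true_duration_days)) df$true_duration_days <- true_duration_days
  new_cohort(df, origin, origin + w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A fitted-model stub with explicit parameters, for hand-arithmetic checks.
make_model <- function(medians, centers_std, mean, sd, cutoff = max(medians)) {
  structure(
    list(
      retention_cutoff_days = cutoff,
      standardization_mean = mean, standardization_sd = sd,
      k_selected = length(medians), centers_std = centers_std,
      median_duration_days = medians,
      silhouette_by_k = stats::setNames(numeric(0), character(0)),
      sampled_gaps = NULL, cluster = NULL, config = see_config()
    ),
    class = "see_model"
  )
}
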