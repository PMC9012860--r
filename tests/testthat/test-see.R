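test_that("refill gaps are per-patient consecutive differences", {
  co <- make_cohort(c("A", "A", "A", "B", "C", "C"),
                    c(0, 30, 90, 10, 0, 60), window_days = 120)
  g <- compute_refill_gaps(co)
  expect_equal(g$gap_days[g$patient_id == "A"], c(30L, 60L))
  expect_equal(g$fill_index[g$patient_id == "A"], c(1L, 2L))
  expect_false("B" %in% g$patient_id)  # single fill, no gap
  expect_equal(g$gap_days[g$patient_id == "C"], 60L)
})

test_that("trim_ecdf keeps the smallest value reaching the retention fraction", {
  g <- data.frame(patient_id = letters[1:10], fill_index = 1L, gap_days = 1:10)
  tr <- trim_ecdf(g, 0.8)
  expect_equal(tr$cutoff_days, 8L)
  expect_setequal(tr$retained$gap_days, 1:8)
  expect_equal(tr$cutoff_days, oracle_trim_cutoff(g$gap_days, 0.8))

  g2 <- data.frame(patient_id = letters[1:10], fill_index = 1L,
                   gap_days = c(rep(30L, 8), 300L, 400L))
  tr2 <- trim_ecdf(g2, 0.8)
  expect_equal(tr2$cutoff_days, 30L)
  expect_setequal(tr2$retained$gap_days, 30L)
  expect_equal(tr2$cutoff_days, oracle_trim_cutoff(g2$gap_days, 0.8))

  # degenerate distribution: everything retained
  g3 <- data.frame(patient_id = letters[1:5], fill_index = 1L,
                   gap_days = rep(30L, 5))
  expect_equal(trim_ecdf(g3, 0.8)$cutoff_days, 30L)
  expect_equal(nrow(trim_ecdf(g3, 0.8)$retained), 5L)

  expect_error(trim_ecdf(g[0, ], 0.8), "no refill gaps")
})

test_that("trim_ecdf retains at least the retention fraction and only drops the largest", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    g <- data.frame(patient_id = as.character(seq_len(n)), fill_index = 1L,
                    gap_days = sample(1:400, n, replace = TRUE))
    r <- runif(1, 0.3, 1)
    tr <- trim_ecdf(g, r)
    expect_gte(nrow(tr$retained) / n, r)
    # downward-closed: every removed gap strictly exceeds every retained gap
    removed <- setdiff(g$gap_days, tr$retained$gap_days)
    if (length(removed)) expect_gt(min(removed), max(tr$retained$gap_days))
    expect_equal(tr$cutoff_days, oracle_trim_cutoff(g$gap_days, r))
  }
})

test_that("sample_random_pairs picks one retained gap per patient, uniformly", {
  g <- data.frame(patient_id = c("A", "A", "A", "B"), fill_index = c(1:3, 1L),
                  gap_days = c(30L, 60L, 90L, 45L))
  draws <- vapply(1:10000, function(s) {
    sample_random_pairs(g, seed = s)$gap_days[1]
  }, integer(1))
  tab <- table(draws)
  # each of A's three gaps with probability 1/3 (binomial 99% bounds)
  bound <- 2.576 * sqrt(10000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(as.numeric(tab) - 10000 / 3) <= bound))

  one <- sample_random_pairs(g, seed = 1)
  expect_equal(nrow(one), 2L)
  expect_equal(one$gap_days[one$patient_id == "B"], 45L)
  expect_identical(one, sample_random_pairs(g, seed = 1))
})

test_that("patients whose gaps all exceeded the cutoff are absent from the sample", {
  g <- data.frame(patient_id = c("A", "A", "B"), fill_index = c(1L, 2L, 1L),
                  gap_days = c(30L, 31L, 400L))
  tr <- trim_ecdf(g, 0.6)
  s <- sample_random_pairs(tr$retained, seed = 2)
  expect_false("B" %in% s$patient_id)
})

test_that("standardize centers, scales and inverts", {
  st <- standardize(c(10, 20, 30))
  expect_equal(st$mean, 20)
  expect_equal(st$sd, 10)
  expect_equal(st$z, c(-1, 0, 1))
  expect_error(standardize(rep(5, 4)), class = "see_degenerate_error")
  set.seed(4)
  x <- rnorm(50, 60, 17)
  st2 <- standardize(x)
  expect_equal(mean(st2$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(st2$z), 1, tolerance = 1e-12)
  expect_equal(st2$z * st2$sd + st2$mean, x)
})

test_that("silhouette K selection recovers well-separated groups", {
  x <- c(28, 30, 32, 88, 90, 92)
  z <- standardize(x)$z
  sel <- select_k_silhouette(z, 2, 10, n_restarts = 20, seed = 1)
  expect_equal(sel$k_selected, 2L)
  expect_equal(sel$cluster, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(sel$k_selected, oracle_select_k(z)$k_selected)

  set.seed(8)
  x3 <- c(30, 60, 90)[rep(1:3, each = 5)] + runif(15, -1, 1)
  z3 <- standardize(x3)$z
  sel3 <- select_k_silhouette(z3, 2, 10, n_restarts = 20, seed = 1)
  expect_equal(sel3$k_selected, 3L)

  expect_error(select_k_silhouette(rep(0, 5)), class = "see_degenerate_error")
})

test_that("K selection matches the exhaustive contiguous-partition oracle", {
  set.seed(7)
  n_checked <- 0
  while (n_checked < 200) {
    n <- sample(4:10, 1)
    x <- round(runif(n, 10, 120), 2)
    if (length(unique(x)) < 3) next
    n_checked <- n_checked + 1
    z <- standardize(x)$z
    sel <- select_k_silhouette(z, 2, 10, n_restarts = 50, seed = n_checked)
    orc <- oracle_select_k(z, 2, 10)
    if (sel$k_selected != orc$k_selected) {
      # distinct K admissible only under an exact silhouette tie
      expect_equal(unname(sel$silhouette_by_k[as.character(sel$k_selected)]),
                   max(orc$silhouette_by_k), tolerance = 1e-8)
    } else {
      expect_equal(sel$k_selected, orc$k_selected)
      expect_equal(unname(sel$silhouette_by_k[as.character(sel$k_selected)]),
                   unname(orc$silhouette_by_k[as.character(orc$k_selected)]),
                   tolerance = 1e-8)
    }
  }
})

test_that("fit_see degenerates gracefully on constant gaps", {
  co <- make_cohort(rep(c("A", "B", "C"), each = 3),
                    rep(c(0, 30, 60), 3), window_days = 90)
  m <- fit_see(co, see_config(seed = 1))
  expect_equal(m$k_selected, 1L)
  expect_equal(m$median_duration_days, 30)
  a <- assign_durations(co, m)
  expect_true(all(a$duration_days == 30))
})

test_that("fit_see recovers two separated gap groups within 2 days", {
  set.seed(12)
  n <- 200
  short <- pmax(23L, pmin(37L, as.integer(round(rnorm(n / 2, 30, 2.5)))))
  long <- pmax(81L, pmin(99L, as.integer(round(rnorm(n / 2, 90, 3)))))
  gaps <- c(short, long)
  day <- unlist(lapply(gaps, function(g) c(0, g, 2 * g)))
  pid <- rep(sprintf("P%03d", seq_len(n)), each = 3)
  co <- make_cohort(pid, day, window_days = 400)
  m <- fit_see(co, see_config(seed = 3))
  expect_equal(m$k_selected, 2L)
  expect_lte(abs(m$median_duration_days[1] - 30), 2)
  expect_lte(abs(m$median_duration_days[2] - 90), 2)
  # model invariants
  expect_true(!is.unsorted(m$median_duration_days))
  expect_true(all(m$median_duration_days <= m$retention_cutoff_days))
  expect_equal(m$k_selected,
               as.integer(names(which.max(m$silhouette_by_k))))
})

test_that("trimming is a no-op when there are no long gaps", {
  set.seed(13)
  gaps <- sample(29:31, 60, replace = TRUE)
  day <- unlist(lapply(gaps, function(g) c(0, g)))
  pid <- rep(sprintf("P%03d", 1:60), each = 2)
  co <- make_cohort(pid, day, window_days = 120)
  m1 <- fit_see(co, see_config(ecdf_retention = 0.8, seed = 9))
  m2 <- fit_see(co, see_config(ecdf_retention = 1.0, seed = 9))
  expect_equal(m1$median_duration_days, m2$median_duration_days)
  expect_equal(m1$k_selected, m2$k_selected)
  expect_equal(m1$sampled_gaps$gap_days, m2$sampled_gaps$gap_days)
})

test_that("cluster medians scale with the data (scale equivariance)", {
  set.seed(14)
  gaps <- c(sample(28:32, 40, TRUE), sample(58:62, 40, TRUE))
  build <- function(g, w) {
    day <- unlist(lapply(g, function(x) c(0, x)))
    make_cohort(rep(sprintf("P%03d", seq_along(g)), each = 2), day,
                window_days = w)
  }
  m1 <- fit_see(build(gaps, 200), see_config(seed = 5))
  m2 <- fit_see(build(gaps * 3L, 600), see_config(seed = 5))
  expect_equal(m2$median_duration_days, 3 * m1$median_duration_days)
  expect_equal(m2$k_selected, m1$k_selected)
})

test_that("assign_durations follows nearest-center arithmetic and the last-fill rule", {
  co <- make_cohort(c("A", "A", "A"), c(0, 31, 62), window_days = 100)
  model <- make_model(medians = c(30, 90), centers_std = c(-1, 1),
                      mean = 60, sd = 30)
  a <- assign_durations(co, model)
  expect_equal(a$cluster_id, c(1L, 1L, NA))
  expect_equal(a$duration_days, c(30, 30, 30))  # last fill inherits
  expect_equal(a$end_day, c(30L, 61L, 92L))
  expect_equal(a$end_of_supply, as.Date("2010-01-01") + c(30, 61, 92))

  # a gap above the cutoff is still assigned (to the largest cluster median)
  co2 <- make_cohort(c("A", "A"), c(0, 200), window_days = 300)
  a2 <- assign_durations(co2, model)
  expect_equal(a2$duration_days[1], 90)

  # single-fill patient gets the global median of medians
  co3 <- make_cohort(c("A", "A", "B"), c(0, 31, 5), window_days = 100)
  a3 <- assign_durations(co3, model)
  expect_equal(a3$duration_days[a3$patient_id == "B"], 60)

  # every fill receives a duration and an end of supply (totality)
  sim <- simulate_cohort(sim_config(n_patients = 60, seed = 17))
  co4 <- suppressMessages(validate_cohort(sim$cohort))
  a4 <- assign_durations(co4, fit_see(co4, see_config(seed = 18)))
  expect_false(anyNA(a4$duration_days))
  expect_false(anyNA(a4$end_of_supply))
})

test_that("assignment ties between equidistant centers go to the smaller center", {
  model <- make_model(medians = c(30, 90), centers_std = c(-1, 1),
                      mean = 60, sd = 30)
  co <- make_cohort(c("A", "A"), c(0, 60), window_days = 100)  # z exactly 0
  a <- assign_durations(co, model)
  expect_equal(a$cluster_id[1], 1L)
  expect_equal(a$duration_days[1], 30)
})

test_that("estimated exposure timelines merge and stay order-invariant", {
  assigned <- data.frame(patient_id = "A", day = c(0L, 20L),
                         end_day = c(30L, 50L))
  tl <- build_exposure_timeline(assigned)
  expect_equal(tl$intervals$start, 0)
  expect_equal(tl$intervals$end, 50)

  assigned2 <- data.frame(patient_id = "A", day = c(0L, 60L),
                          end_day = c(30L, 90L))
  tl2 <- build_exposure_timeline(assigned2)
  expect_equal(nrow(tl2$intervals), 2L)
  expect_false(exposed_at(tl2, "A", 45))

  # permuting rows changes nothing
  perm <- assigned2[2:1, ]
  expect_equal(build_exposure_timeline(perm)$intervals, tl2$intervals)

  # empty patient: present in the patient set, never exposed
  tl3 <- new_timeline(data.frame(patient_id = character(), start = numeric(),
                                 end = numeric()), patients = "Z")
  expect_false(exposed_at(tl3, "Z", 10))
})
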