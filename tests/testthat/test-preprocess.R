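# independent brute-force lag oracle: plain loop over lags on value vectors
# sharing a common grid (t0 = 0 both), picking the max-correlation lag with
# the smallest-|lag|-then-negative tie-break
oracle_lag <- function(ref, wear, max_lag) {
  best_lag <- NA_integer_; best_r <- -Inf
  for (L in -max_lag:max_lag) {
    n <- length(ref)
    i <- max(1, 1 - L):min(n, length(wear) - L)
    if (length(i) < 60) next
    a <- ref[i]; b <- wear[i + L]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 60) next
    r <- suppressWarnings(stats::cor(a[ok], b[ok]))
    if (is.na(r)) next
    better <- r > best_r ||
      (r == best_r && (abs(L) < abs(best_lag) || (abs(L) == abs(best_lag) && L < best_lag)))
    if (better) { best_r <- r; best_lag <- L }
  }
  best_lag
}

test_that("estimate_lag recovers a known shift and matches the brute-force oracle", {
  set.seed(101)
  x <- ar1_track(2000)
  ref <- make_series(round(x[1:1500], 4), device = "reference")
  # identical series: lag 0
  expect_identical(estimate_lag(make_series(round(x[1:1500], 4)), ref, max_lag_s = 60), 0L)
  # wearable delayed by 37 s: its sample stamped t shows the signal of t - 37
  wear <- make_series(round(c(rep(x[1], 37), x[1:1463]), 4))
  est <- estimate_lag(wear, ref, max_lag_s = 300)
  expect_identical(est, 37L)
  expect_identical(est, oracle_lag(ref$values, wear$values, 300))
})

test_that("estimate_lag rejects degenerate or non-overlapping signals", {
  const <- make_series(rep(70, 300))
  expect_error(estimate_lag(const, make_series(rep(70, 300), device = "reference")),
               "degenerate")
  set.seed(3)
  a <- make_series(ar1_track(300))
  b <- make_series(ar1_track(300), device = "reference", t0 = 5000L)
  expect_error(estimate_lag(a, b, max_lag_s = 100), "insufficient overlap")
})

test_that("estimate_lag is shift-equivariant in the wearable clock", {
  set.seed(77)
  x <- ar1_track(1200)
  ref <- make_series(x + rnorm(1200, 0, 0.5), device = "reference")
  wear0 <- make_series(x + rnorm(1200, 0, 0.5))
  base <- estimate_lag(wear0, ref, max_lag_s = 120)
  for (k in c(-40L, -7L, 13L, 60L)) {
    shifted <- wear0
    shifted$t0 <- shifted$t0 + k
    expect_identical(estimate_lag(shifted, ref, max_lag_s = 120), base + k)
  }
})

test_that("apply_lag crops to the overlap and errors when there is none", {
  v <- seq(60, 60 + 99)
  wear <- make_series(v)
  ref <- make_series(v, device = "reference")
  al0 <- apply_lag(wear, ref, 0)
  expect_length(al0$reference$values, 100)
  expect_equal(series_times(al0$wearable), series_times(al0$reference))

  al10 <- apply_lag(wear, ref, 10)
  expect_length(al10$reference$values, 90)
  # wearable sample stamped t+10 lands on reference second t
  expect_equal(al10$wearable$values[1], v[11])
  expect_equal(al10$reference$values[1], v[1])

  expect_error(apply_lag(wear, ref, 200), "no overlap")
  expect_error(apply_lag(wear, ref, 400), "exceeds the configured maximum")
})

test_that("quality_mask keeps only present samples at the cutoff", {
  s <- make_series(c(60, 61, 62, NA, 64), c(4, 4, 3, 0, 4))
  expect_equal(quality_mask(s), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_true(all(quality_mask(make_series(60:64, rep(4, 5)))))
  expect_true(all(quality_mask(s, min_quality = 0)[-4]))  # only missing fails at 0
})

test_that("short or absent reference recordings are excluded per vital", {
  mk <- function(pid, hr_len, rr_len = NULL) {
    args <- list(patient_id = pid)
    args$hr_reference <- make_series(rep(70, hr_len), patient_id = pid, device = "reference")
    args$hr_wearable <- make_series(rep(70, hr_len), patient_id = pid)
    if (!is.null(rr_len)) {
      args$rr_reference <- make_series(rep(14, rr_len), patient_id = pid,
                                       device = "reference", vital = "RR")
    }
    do.call(patient_recording, args)
  }
  cohort <- list(
    mk("short", 14 * 60),           # 14 min: out for HR, no RR reference
    mk("edge", 15 * 60, 15 * 60),   # exactly 15 min: retained for both
    mk("hr_only", 16 * 60)          # kept for HR, excluded for RR (no reference)
  )
  res <- exclude_short_recordings(cohort)
  expect_setequal(res$eligible$HR, c("edge", "hr_only"))
  expect_setequal(res$eligible$RR, "edge")
  expect_equal(
    res$exclusions$reason[res$exclusions$patient_id == "hr_only" &
                            res$exclusions$vital == "RR"],
    "no reference")
  expect_match(
    res$exclusions$reason[res$exclusions$patient_id == "short" &
                            res$exclusions$vital == "HR"],
    "shorter than")
})

test_that("make_pairs keeps the conjunction of the masks", {
  wear <- make_series(c(60, 61, 62))
  ref <- make_series(c(60, 61, 62), device = "reference")
  al <- apply_lag(wear, ref, 0)
  pp <- make_pairs(al, wear_mask = c(TRUE, TRUE, FALSE), ref_mask = c(TRUE, FALSE, TRUE))
  expect_equal(nrow(pp$pairs), 1)
  expect_equal(pp$pairs$t_s, 0)
  expect_equal(pp$counts$n_both, 1)

  all_pp <- make_pairs(al)
  expect_equal(nrow(all_pp$pairs), 3)

  none <- make_pairs(al, wear_mask = c(TRUE, FALSE, TRUE), ref_mask = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(none$pairs), 0)
})

test_that("pair count equals the popcount of the mask conjunction", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:300, 1)
    v <- runif(n, 50, 120)
    al <- apply_lag(make_series(v), make_series(v, device = "reference"), 0)
    wm <- runif(n) < runif(1)
    rm_ <- runif(n) < runif(1)
    pp <- make_pairs(al, wm, rm_)
    manual <- sum(wm & rm_)  # direct loop oracle
    expect_equal(nrow(pp$pairs), manual)
    expect_equal(pp$counts$n_both, manual)
    expect_lte(pp$counts$n_both, pp$counts$n_overlap)
  }
})

test_that("coverage_and_gaps counts runs of low quality", {
  m <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 30), rep(FALSE, 30))
  cov <- coverage_and_gaps(m)
  expect_equal(cov$pct_good, 60)
  expect_equal(sort(cov$gap_lengths), c(10L, 30L))
  expect_equal(cov$pct_gaps_lt_60s, 100)
  expect_equal(cov$max_gap_s, 30L)

  all_good <- coverage_and_gaps(rep(TRUE, 50))
  expect_equal(all_good$pct_good, 100)
  expect_length(all_good$gap_lengths, 0)
  expect_equal(all_good$pct_gaps_lt_60s, 100)

  leading <- coverage_and_gaps(c(rep(FALSE, 70), rep(TRUE, 30)))
  expect_equal(leading$gap_lengths, 70L)
  expect_equal(leading$pct_gaps_lt_60s, 0)
})

test_that("coverage accounting always balances", {
  set.seed(9)
  for (i in 1:40) {
    m <- runif(sample(1:500, 1)) < runif(1)
    cov <- coverage_and_gaps(m)
    expect_equal(cov$n_seconds_good + sum(cov$gap_lengths), cov$n_seconds_total)
    expect_gte(cov$pct_good, 0); expect_lte(cov$pct_good, 100)
    expect_equal(cov$max_gap_s, if (length(cov$gap_lengths)) max(cov$gap_lengths) else 0L)
  }
})

test_that("cohort coverage summary uses interpolated quartiles", {
  mk <- function(p) coverage_and_gaps(c(rep(TRUE, p), rep(FALSE, 100 - p)))
  s <- cohort_coverage_summary(lapply(c(90, 96, 100), mk))
  expect_equal(s$median_pct_good, 96)

  single <- cohort_coverage_summary(list(mk(85)))
  expect_equal(single$median_pct_good, 85)
  expect_equal(diff(single$iqr_pct_good), 0)

  uniform <- cohort_coverage_summary(lapply(0:100, mk))
  expect_equal(uniform$median_pct_good, 50)
})
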