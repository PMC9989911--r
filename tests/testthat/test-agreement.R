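# classic Bland-Altman by direct formula: one observation per subject
classic_ba <- function(d, z = 1.96) {
  list(bias = mean(d), sd = stats::sd(d),
       lower = mean(d) - z * stats::sd(d), upper = mean(d) + z * stats::sd(d))
}

test_that("with one observation per patient the estimator reduces to classic Bland-Altman", {
  d <- list(a = -1, b = 0, c = 1)
  res <- bland_altman_repeated(d)
  expect_equal(res$bias, 0)
  expect_equal(res$sd_total, 1)
  expect_equal(res$loa_lower, -1.96)
  expect_equal(res$loa_upper, 1.96)

  set.seed(21)
  for (i in 1:10) {
    dd <- rnorm(sample(5:50, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    res <- bland_altman_repeated(as.list(dd))
    ora <- classic_ba(dd)
    expect_equal(res$bias, ora$bias, tolerance = 1e-10)
    expect_equal(res$sd_total, ora$sd, tolerance = 1e-10)
    expect_equal(res$loa_lower, ora$lower, tolerance = 1e-10)
    expect_equal(res$loa_upper, ora$upper, tolerance = 1e-10)
  }
})

test_that("degenerate inputs behave as documented", {
  res <- bland_altman_repeated(replicate(3, rep(0, 10), simplify = FALSE))
  expect_equal(res$bias, 0)
  expect_equal(res$loa_lower, 0)
  expect_equal(res$loa_upper, 0)
  expect_error(bland_altman_repeated(list(rnorm(10))), "classic")
})

test_that("variance components recover the generative model (closed-form oracle)", {
  # d_ij = delta_i + eps_ij, delta ~ N(0.5, 1), eps ~ N(0, 4):
  # bias -> 0.5, sd_total -> sqrt(5), LoA -> 0.5 -/+ 1.96*sqrt(5)
  set.seed(1)
  n <- 200; m <- 500
  delta <- rnorm(n, 0.5, 1)
  diffs <- lapply(delta, function(b) b + rnorm(m, 0, 2))
  res <- bland_altman_repeated(diffs)
  expect_equal(res$bias, 0.5, tolerance = 0.25)          # ~3.5 SE of the mean
  expect_equal(res$sd_total, sqrt(5), tolerance = 0.04)  # relative ~1.8%
  expect_equal(res$loa_upper, 0.5 + 1.96 * sqrt(5), tolerance = 0.3)
  expect_equal(res$loa_lower, 0.5 - 1.96 * sqrt(5), tolerance = 0.3)
  expect_equal(res$sd_total^2, res$sd_between^2 + res$sd_within^2, tolerance = 1e-10)
})

test_that("MOVER intervals collapse to the bias t-interval when sd_total is 0", {
  m <- c(10L, 10L, 10L)
  ci <- mover_ci_loa(bias = 1.5, sd_between = 0, sd_within = 0, m_per_patient = m)
  expect_equal(ci$ci_loa_lower, ci$ci_bias)
  expect_equal(ci$ci_loa_upper, ci$ci_bias)
  expect_equal(unname(ci$ci_bias), c(1.5, 1.5))
})

test_that("MOVER intervals bracket their limit and shrink with alpha", {
  set.seed(8)
  diffs <- lapply(rnorm(20, 0.3, 1), function(b) b + rnorm(50, 0, 2))
  res <- bland_altman_repeated(diffs)
  ci05 <- mover_ci_loa(res$bias, res$sd_between, res$sd_within, res$m_per_patient,
                       alpha = 0.05)
  ci50 <- mover_ci_loa(res$bias, res$sd_between, res$sd_within, res$m_per_patient,
                       alpha = 0.5)
  expect_lt(ci05$ci_loa_upper["low"], res$loa_upper)
  expect_gt(ci05$ci_loa_upper["high"], res$loa_upper)
  expect_lt(ci05$ci_loa_lower["low"], res$loa_lower)
  expect_gt(ci05$ci_loa_lower["high"], res$loa_lower)
  # strict containment of the 50% interval in the 95% interval
  expect_gt(ci50$ci_loa_upper["low"], ci05$ci_loa_upper["low"])
  expect_lt(ci50$ci_loa_upper["high"], ci05$ci_loa_upper["high"])
  expect_gt(ci50$ci_loa_lower["low"], ci05$ci_loa_lower["low"])
  expect_lt(ci50$ci_loa_lower["high"], ci05$ci_loa_lower["high"])
})

test_that("pooled Pearson correlation matches the direct product-moment formula", {
  expect_equal(pooled_pearson(c(60, 70, 80), c(60, 70, 80)), 1)
  expect_equal(pooled_pearson(c(60, 70, 80), -c(60, 70, 80) + 200), -1)

  ref <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  wear <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  # hand formula oracle
  n <- length(ref)
  num <- sum(ref * wear) - n * mean(ref) * mean(wear)
  den <- sqrt((sum(ref^2) - n * mean(ref)^2) * (sum(wear^2) - n * mean(wear)^2))
  expect_equal(pooled_pearson(ref, wear), num / den, tolerance = 1e-12)

  expect_error(pooled_pearson(rep(70, 5), 1:5), "zero variance")
  expect_error(pooled_pearson(1, 2), "at least 2")
})

test_that("pct_within counts inclusively and is symmetric in the devices", {
  expect_equal(pct_within(c(0, 3, 6), tolerance = 5), 100 * 2 / 3)
  expect_equal(pct_within(5, tolerance = 5), 100)   # inclusive boundary
  expect_equal(pct_within(c(6, 7, 8), tolerance = 5), 0)
  expect_error(pct_within(numeric(0), tolerance = 5), "no pairs")

  set.seed(14)
  for (i in 1:20) {
    ref <- runif(50, 50, 120); wear <- ref + rnorm(50, 0, 4)
    expect_equal(pct_within(ref, wear, tolerance = 5),
                 pct_within(wear, ref, tolerance = 5))
  }
})

test_that("agreement_analysis assembles a coherent result", {
  set.seed(30)
  pairs <- do.call(rbind, lapply(1:8, function(i) {
    ref <- runif(100, 60, 100)
    data.frame(patient_id = sprintf("p%02d", i), ref = ref,
               wear = ref + rnorm(1, 0, 1) + rnorm(100, 0, 2))
  }))
  res <- agreement_analysis(pairs, vital = "HR")
  expect_equal(res$threshold, 5)
  expect_equal(res$n_pairs, 800)
  expect_lte(res$loa_lower, res$bias)
  expect_gte(res$loa_upper, res$bias)
  expect_equal(res$loa_upper - res$loa_lower, 2 * 1.96 * res$sd_total)
  expect_true(res$ci_loa_upper["low"] <= res$loa_upper &&
                res$loa_upper <= res$ci_loa_upper["high"])
})
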