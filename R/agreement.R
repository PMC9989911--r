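#' Repeated-measures Bland-Altman limits of agreement
#'
#' Classic Bland-Altman limits (mean difference plus/minus `z` standard
#' deviations) understate the difference SD when each subject contributes
#' many correlated observations. This estimator splits the variance of a
#' single difference into a between-patient component (each patient's device
#' offset) and a within-patient component (second-to-second error) by
#' one-way random-effects method of moments, using the harmonic mean of the
#' per-patient counts to correct unbalanced designs.
#'
#' With per-patient means \eqn{\bar d_i}, the bias is the unweighted mean of
#' the \eqn{\bar d_i}; the within variance is the pooled variance around the
#' patient means; the between variance is
#' \eqn{\mathrm{var}(\bar d_i) - s_w^2/m_h} (harmonic mean \eqn{m_h}),
#' truncated at 0; and the SD of a single difference is
#' \eqn{\sqrt{s_b^2 + s_w^2}}. When every patient contributes exactly one
#' observation the estimator reduces to the classic Bland-Altman formula.
#'
#' @param diffs_by_patient named list (or a factor-split) of numeric
#'   difference vectors, one element per patient, differences taken as
#'   wearable minus reference.
#' @param z normal quantile defining the limits (1.96 for 95% limits).
#' @return An object of class `agreement_result` with `n_patients`,
#'   `n_pairs`, `m_per_patient`, `bias`, `sd_within`, `sd_between`,
#'   `sd_total`, `var_means` (variance of the per-patient mean differences),
#'   `loa_lower`, `loa_upper`, `z`.
#' @references Bland & Altman (1986) Lancet; Bland & Altman (2007) J
#'   Biopharm Stat (multiple observations per individual); Zou (2013) Stat
#'   Methods Med Res (variance components and MOVER intervals for repeated-
#'   measures limits of agreement).
#' @export
bland_altman_repeated <- function(diffs_by_patient, z = 1.96) {
  diffs_by_patient <- lapply(diffs_by_patient, function(d) as.numeric(d[!is.na(d)]))
  diffs_by_patient <- diffs_by_patient[vapply(diffs_by_patient, length, integer(1)) > 0L]
  n <- length(diffs_by_patient)
  if (n < 2L) {
    stop("need at least 2 patients; with a single patient use the classic ",
         "(non-repeated) Bland-Altman estimator on its differences", call. = FALSE)
  }
  m <- vapply(diffs_by_patient, length, integer(1))
  dbar <- vapply(diffs_by_patient, mean, numeric(1))
  bias <- mean(dbar)
  var_means <- stats::var(dbar)
  df_w <- sum(m - 1L)
  var_within <- if (df_w > 0L) {
    sum(vapply(diffs_by_patient, function(d) sum((d - mean(d))^2), numeric(1))) / df_w
  } else 0
  m_h <- n / sum(1 / m)  # harmonic mean of per-patient counts
  var_between <- max(0, var_means - var_within / m_h)
  sd_total <- sqrt(var_between + var_within)
  structure(
    list(
      n_patients = n,
      n_pairs = sum(m),
      m_per_patient = m,
      bias = bias,
      sd_within = sqrt(var_within),
      sd_between = sqrt(var_between),
      sd_total = sd_total,
      var_means = var_means,
      loa_lower = bias - z * sd_total,
      loa_upper = bias + z * sd_total,
      z = z
    ),
    class = "agreement_result"
  )
}

#' MOVER confidence intervals for repeated-measures limits of agreement
#'
#' Builds a confidence interval around each limit of agreement by the Method
#' Of Variance Estimates Recovery: a t-based interval for the bias and
#' chi-square intervals for the two variance components (variance of the
#' per-patient means, df `n - 1`; within-patient variance, df `N - n`) are
#' recovered into an interval for `bias +/- z * sd_total`. The total-variance
#' interval combines the component intervals for
#' \eqn{s_{\bar d}^2 + (1 - 1/m_h)\, s_w^2} (the varying-true-value
#' decomposition, appropriate when the underlying vital changes over the
#' recording); its center is the truncation-consistent total variance so the
#' interval always contains the reported limit.
#'
#' @param bias mean difference (wearable minus reference).
#' @param sd_between,sd_within variance-component SDs from
#'   [bland_altman_repeated()].
#' @param m_per_patient integer vector of per-patient pair counts.
#' @param alpha two-sided error rate (default 0.05 for 95% intervals).
#' @param z limit multiplier, as in [bland_altman_repeated()].
#' @return List with `ci_loa_lower` and `ci_loa_upper`, each a named
#'   length-2 vector `c(low, high)` bracketing the respective limit, and
#'   `ci_bias` for the bias itself. With `sd_total` 0 both limit intervals
#'   collapse to the bias interval.
#' @export
mover_ci_loa <- function(bias, sd_between, sd_within, m_per_patient,
                         alpha = 0.05, z = 1.96) {
  m <- as.integer(m_per_patient)
  n <- length(m)
  if (n < 2L) stop("need per-patient counts for at least 2 patients", call. = FALSE)
  N <- sum(m)
  m_h <- n / sum(1 / m)
  var_b <- sd_between^2
  var_w <- sd_within^2
  # variance of the per-patient means implied by the (truncated) components
  var_means <- var_b + var_w / m_h
  var_total <- var_b + var_w

  # bias CI: t interval on the per-patient means
  se_bias <- sqrt(var_means / n)
  tq <- stats::qt(1 - alpha / 2, df = n - 1L)
  l_mu <- bias - tq * se_bias
  u_mu <- bias + tq * se_bias
  ci_bias <- c(low = l_mu, high = u_mu)

  if (var_total <= 0) {
    return(list(ci_loa_lower = ci_bias, ci_loa_upper = ci_bias, ci_bias = ci_bias))
  }

  # chi-square CIs for the two variance components of
  #   var_means + (1 - 1/m_h) * var_w
  df1 <- n - 1L
  comp1 <- var_means
  l1 <- comp1 * df1 / stats::qchisq(1 - alpha / 2, df1)
  u1 <- comp1 * df1 / stats::qchisq(alpha / 2, df1)
  df2 <- N - n
  comp2 <- (1 - 1 / m_h) * var_w
  if (df2 > 0L && comp2 > 0) {
    l2 <- comp2 * df2 / stats::qchisq(1 - alpha / 2, df2)
    u2 <- comp2 * df2 / stats::qchisq(alpha / 2, df2)
  } else {
    comp2 <- 0; l2 <- 0; u2 <- 0
  }
  half_low <- sqrt((comp1 - l1)^2 + (comp2 - l2)^2)
  half_high <- sqrt((u1 - comp1)^2 + (u2 - comp2)^2)
  l_var <- max(0, var_total - half_low)
  u_var <- var_total + half_high

  sd_tot <- sqrt(var_total)
  l_sd <- z * sqrt(l_var)
  u_sd <- z * sqrt(u_var)
  zs <- z * sd_tot

  upper_pt <- bias + zs
  ci_upper <- c(
    low = upper_pt - sqrt((bias - l_mu)^2 + (zs - l_sd)^2),
    high = upper_pt + sqrt((u_mu - bias)^2 + (u_sd - zs)^2)
  )
  lower_pt <- bias - zs
  ci_lower <- c(
    low = lower_pt - sqrt((bias - l_mu)^2 + (u_sd - zs)^2),
    high = lower_pt + sqrt((u_mu - bias)^2 + (zs - l_sd)^2)
  )
  list(ci_loa_lower = ci_lower, ci_loa_upper = ci_upper, ci_bias = ci_bias)
}

#' Pooled Pearson correlation over all pairs
#'
#' The correlation is computed over the entire pooled data set, not averaged
#' per patient, so it mixes between- and within-patient variation.
#'
#' @param ref,wear numeric vectors of paired reference and wearable values.
#' @return Pearson product-moment correlation.
#' @export
pooled_pearson <- function(ref, wear) {
  ok <- !is.na(ref) & !is.na(wear)
  ref <- ref[ok]; wear <- wear[ok]
  if (length(ref) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(ref) == 0 || stats::sd(wear) == 0) {
    stop("undefined correlation: zero variance in one coordinate", call. = FALSE)
  }
  stats::cor(ref, wear)
}

#' Percentage of pairs within a clinical-acceptability threshold
#'
#' @param ref,wear numeric vectors of paired values, or `wear` may be
#'   omitted and `ref` interpreted as the differences directly.
#' @param tolerance acceptability threshold in the vital's units (5 bpm for
#'   heart rate, 3 rpm for respiratory rate are the usual clinical choices);
#'   the comparison is inclusive.
#' @return Percentage in `[0, 100]`.
#' @export
pct_within <- function(ref, wear = NULL, tolerance) {
  d <- if (is.null(wear)) ref else wear - ref
  d <- d[!is.na(d)]
  if (!length(d)) stop("no pairs to evaluate", call. = FALSE)
  100 * mean(abs(d) <= tolerance)
}

#' Full agreement analysis of pooled paired points
#'
#' Convenience wrapper running [bland_altman_repeated()], [mover_ci_loa()],
#' [pooled_pearson()] and [pct_within()] on a pooled pairs table.
#'
#' @param pairs data frame with columns `patient_id`, `ref`, `wear` (e.g.
#'   row-bound `pairs` elements of [make_pairs()] results).
#' @param vital label stored in the result.
#' @param threshold within-threshold tolerance in the vital's units.
#' @param z limit multiplier (default 1.96).
#' @param alpha error rate of the MOVER intervals (default 0.05).
#' @return An `agreement_result` extended with `vital`, `threshold`,
#'   `pearson_r`, `pct_within_threshold`, `ci_loa_lower`, `ci_loa_upper`,
#'   `ci_bias`.
#' @export
agreement_analysis <- function(pairs, vital = "HR", threshold = if (vital == "HR") 5 else 3,
                               z = 1.96, alpha = 0.05) {
  stopifnot(all(c("patient_id", "ref", "wear") %in% names(pairs)))
  d <- pairs$wear - pairs$ref
  ba <- bland_altman_repeated(split(d, pairs$patient_id), z = z)
  ci <- mover_ci_loa(ba$bias, ba$sd_between, ba$sd_within, ba$m_per_patient,
                     alpha = alpha, z = z)
  ba$vital <- vital
  ba$threshold <- threshold
  ba$pearson_r <- pooled_pearson(pairs$ref, pairs$wear)
  ba$pct_within_threshold <- pct_within(pairs$ref, pairs$wear, tolerance = threshold)
  ba$ci_loa_lower <- ci$ci_loa_lower
  ba$ci_loa_upper <- ci$ci_loa_upper
  ba$ci_bias <- ci$ci_bias
  ba
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result>%s %d patients, %d pairs\n",
              if (!is.null(x$vital)) paste0(" ", x$vital, ","), x$n_patients, x$n_pairs))
  cat(sprintf("  bias %.3f (sd_total %.3f = between %.3f + within %.3f)\n",
              x$bias, x$sd_total, x$sd_between, x$sd_within))
  fmt_ci <- function(ci) if (is.null(ci)) "" else sprintf(" (95%% CI %.2f to %.2f)", ci[1], ci[2])
  cat(sprintf("  limits of agreement %.3f%s to %.3f%s\n",
              x$loa_lower, fmt_ci(x$ci_loa_lower), x$loa_upper, fmt_ci(x$ci_loa_upper)))
  if (!is.null(x$pearson_r)) {
    cat(sprintf("  Pearson r %.3f; %.1f%% within %g %s\n", x$pearson_r,
                x$pct_within_threshold, x$threshold,
                if (identical(x$vital, "RR")) "rpm" else "bpm"))
  }
  invisible(x)
}
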