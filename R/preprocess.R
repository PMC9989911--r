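#' Estimate the wearable clock offset by cross-correlation
#'
#' The wearable and reference devices are started independently, so their
#' streams disagree by a constant clock offset. The offset is estimated on
#' the heart-rate channel (the most autocorrelated and best-covered signal)
#' as the integer lag maximizing the normalized cross-correlation of the
#' mean-centered series, with missing samples excluded pairwise.
#'
#' A returned lag `L` means the wearable stream runs `L` seconds late: the
#' wearable sample stamped `t + L` corresponds to the reference sample
#' stamped `t`. Ties in the correlation are broken toward the smallest
#' absolute lag, then toward the negative lag — devices started
#' near-simultaneously make small offsets the more plausible explanation.
#'
#' @param wearable_hr,reference_hr heart-rate [vital_series].
#' @param max_lag_s half-width of the lag search window in seconds.
#' @param min_overlap_s minimum number of pairwise-complete samples a
#'   candidate lag must have to be considered (default 60).
#' @return Integer lag in seconds.
#' @export
estimate_lag <- function(wearable_hr, reference_hr, max_lag_s = 300,
                         min_overlap_s = 60) {
  stopifnot(inherits(wearable_hr, "vital_series"), inherits(reference_hr, "vital_series"))
  wv <- wearable_hr$values
  rv <- reference_hr$values
  if (stats::sd(wv, na.rm = TRUE) == 0 || stats::sd(rv, na.rm = TRUE) == 0 ||
      sum(!is.na(wv)) < 2L || sum(!is.na(rv)) < 2L) {
    stop("degenerate signal: zero variance after centering; cannot synchronize",
         call. = FALSE)
  }
  lags <- -max_lag_s:max_lag_s
  nr <- length(rv)
  nw <- length(wv)
  # offset of the wearable grid relative to the reference grid
  off <- wearable_hr$t0 - reference_hr$t0
  cors <- rep(NA_real_, length(lags))
  npair <- integer(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    # reference index i pairs with wearable index i + shift
    shift <- L - off
    i_lo <- max(1L, 1L - shift)
    i_hi <- min(nr, nw - shift)
    if (i_hi - i_lo + 1L < min_overlap_s) next
    a <- rv[i_lo:i_hi]
    b <- wv[(i_lo + shift):(i_hi + shift)]
    ok <- !is.na(a) & !is.na(b)
    npair[k] <- sum(ok)
    if (npair[k] < min_overlap_s) next
    sa <- stats::sd(a[ok]); sb <- stats::sd(b[ok])
    if (sa == 0 || sb == 0) next
    cors[k] <- stats::cor(a[ok], b[ok])
  }
  if (all(is.na(cors))) {
    if (max(npair) < min_overlap_s) {
      stop("insufficient overlap: fewer than ", min_overlap_s,
           " pairwise-complete samples at every candidate lag", call. = FALSE)
    }
    stop("degenerate signal: zero variance in every candidate overlap", call. = FALSE)
  }
  best <- which(cors == max(cors, na.rm = TRUE))
  best <- best[order(abs(lags[best]), lags[best])]
  as.integer(lags[best[1L]])
}

#' Align a wearable stream onto the reference clock
#'
#' Shifts the wearable grid by the estimated (or manually overridden) lag and
#' crops both series to their common overlap, producing the shared grid on
#' which all downstream pairing happens. The respiratory-rate channel of the
#' same patient reuses the lag estimated on heart rate: both streams come
#' from one device clock.
#'
#' @param wearable,reference [vital_series] of the same vital.
#' @param lag_s integer lag from [estimate_lag()] (or a manual override).
#' @param max_lag_s sanity bound on `|lag_s|`.
#' @return An `aligned_pair`: list with `patient_id`, `vital`, `lag_s`, and
#'   the cropped `reference` and `wearable` series on identical grids.
#' @export
apply_lag <- function(wearable, reference, lag_s, max_lag_s = 300) {
  stopifnot(inherits(wearable, "vital_series"), inherits(reference, "vital_series"))
  lag_s <- as.integer(lag_s)
  if (abs(lag_s) > max_lag_s) {
    stop("|lag_s| exceeds the configured maximum of ", max_lag_s, " s", call. = FALSE)
  }
  w <- wearable
  w$t0 <- w$t0 - lag_s  # the wearable ran lag_s seconds late
  from <- max(w$t0, reference$t0)
  to <- min(w$t0 + length(w$values) - 1L, reference$t0 + length(reference$values) - 1L)
  if (from > to) stop("no overlap between the series after applying the lag", call. = FALSE)
  structure(
    list(
      patient_id = reference$patient_id,
      vital = reference$vital,
      lag_s = lag_s,
      reference = series_window(reference, from, to),
      wearable = series_window(w, from, to)
    ),
    class = "aligned_pair"
  )
}

#' High-quality sample mask
#'
#' Only samples at the top of the wearable's 0-4 quality index (and valid
#' reference samples, flagged 4) count as high quality.
#'
#' @param series a [vital_series].
#' @param min_quality minimum quality index to accept (default 4).
#' @return Logical vector: `TRUE` where quality passes and the value is
#'   present.
#' @export
quality_mask <- function(series, min_quality = 4) {
  stopifnot(inherits(series, "vital_series"))
  series$quality >= min_quality & !is.na(series$values)
}

#' Drop patients with too little reference data
#'
#' Eligibility is decided per vital: a patient is dropped from a vital's
#' analysis when the reference recording for that vital is absent or spans
#' fewer than `min_minutes` minutes. A recording of exactly `min_minutes` is
#' retained (the rule is "shorter than").
#'
#' @param cohort list of [patient_recording] objects.
#' @param min_minutes minimum reference recording length in minutes
#'   (default 15).
#' @return List with `eligible` (named list `HR`/`RR` of retained patient
#'   ids) and `exclusions` (data frame `patient_id`, `vital`, `reason`).
#' @export
exclude_short_recordings <- function(cohort, min_minutes = 15) {
  excl <- list()
  eligible <- list(HR = character(), RR = character())
  ref_slot <- c(HR = "hr_reference", RR = "rr_reference")
  for (rec in cohort) {
    for (vital in c("HR", "RR")) {
      s <- rec[[ref_slot[[vital]]]]
      if (is.null(s)) {
        excl[[length(excl) + 1L]] <- data.frame(
          patient_id = rec$patient_id, vital = vital, reason = "no reference")
      } else if (length(s$values) < min_minutes * 60) {
        excl[[length(excl) + 1L]] <- data.frame(
          patient_id = rec$patient_id, vital = vital,
          reason = sprintf("reference shorter than %g minutes", min_minutes))
      } else {
        eligible[[vital]] <- c(eligible[[vital]], rec$patient_id)
      }
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), vital = character(), reason = character())
  list(eligible = eligible, exclusions = exclusions)
}

#' Build dual-quality paired points from an aligned pair
#'
#' Keeps the seconds where both the wearable and the reference sample pass
#' their quality masks, and reports the per-device and joint availability
#' counts over the aligned overlap.
#'
#' @param aligned an `aligned_pair` from [apply_lag()].
#' @param wear_mask,ref_mask logical masks on the aligned grid; default
#'   [quality_mask()] of each member series.
#' @param min_quality wearable quality cutoff used for the default masks.
#' @return A `paired_points` object: list with `patient_id`, `vital`,
#'   `pairs` (data frame `t_s`, `ref`, `wear`) and `counts`
#'   (`n_overlap`, `n_good_wearable`, `n_good_reference`, `n_both`).
#' @export
make_pairs <- function(aligned, wear_mask = NULL, ref_mask = NULL, min_quality = 4) {
  stopifnot(inherits(aligned, "aligned_pair"))
  if (is.null(wear_mask)) wear_mask <- quality_mask(aligned$wearable, min_quality)
  if (is.null(ref_mask)) ref_mask <- quality_mask(aligned$reference, 4)
  n <- length(aligned$reference$values)
  stopifnot(length(wear_mask) == n, length(ref_mask) == n)
  both <- wear_mask & ref_mask
  structure(
    list(
      patient_id = aligned$patient_id,
      vital = aligned$vital,
      pairs = data.frame(
        t_s = series_times(aligned$reference)[both],
        ref = aligned$reference$values[both],
        wear = aligned$wearable$values[both]
      ),
      counts = list(
        n_overlap = n,
        n_good_wearable = sum(wear_mask),
        n_good_reference = sum(ref_mask),
        n_both = sum(both)
      )
    ),
    class = "paired_points"
  )
}

#' Coverage and gap-length statistics of a quality mask
#'
#' A gap is a maximal run of low-quality seconds (leading and trailing runs
#' count). Coverage narratives for wearable monitors are usually framed on
#' the device's own availability, so the mask is typically the wearable
#' quality mask alone, not the both-good conjunction.
#'
#' @param mask logical vector, `TRUE` = high-quality second.
#' @return A `coverage_result`: list with `n_seconds_total`,
#'   `n_seconds_good`, `pct_good`, `gap_lengths` (integer vector),
#'   `pct_gaps_lt_60s` (100 when there are no gaps), `max_gap_s`.
#' @export
coverage_and_gaps <- function(mask) {
  mask <- as.logical(mask)
  if (length(mask) < 1L || anyNA(mask)) {
    stop("mask must be a nonempty logical vector without NA", call. = FALSE)
  }
  r <- rle(mask)
  gaps <- r$lengths[!r$values]
  structure(
    list(
      n_seconds_total = length(mask),
      n_seconds_good = sum(mask),
      pct_good = 100 * mean(mask),
      gap_lengths = as.integer(gaps),
      pct_gaps_lt_60s = if (length(gaps)) 100 * mean(gaps < 60) else 100,
      max_gap_s = if (length(gaps)) max(gaps) else 0L
    ),
    class = "coverage_result"
  )
}

#' Cohort-level coverage summary
#'
#' Median and interquartile range (linear-interpolation quartiles) of the
#' per-patient percentage of high-quality seconds, plus pooled gap-length
#' statistics across patients.
#'
#' @param coverages list of `coverage_result` objects, one per patient.
#' @return List with `n_patients`, `median_pct_good`, `iqr_pct_good`
#'   (length-2, 25th and 75th percentile), pooled `pct_gaps_lt_60s`,
#'   `max_gap_s` and `min_gap_s`.
#' @export
cohort_coverage_summary <- function(coverages) {
  if (!length(coverages)) stop("need at least one patient", call. = FALSE)
  pct <- vapply(coverages, function(x) x$pct_good, numeric(1))
  gaps <- unlist(lapply(coverages, function(x) x$gap_lengths))
  q <- stats::quantile(pct, c(0.25, 0.5, 0.75), names = FALSE)
  list(
    n_patients = length(coverages),
    median_pct_good = q[2L],
    iqr_pct_good = q[c(1L, 3L)],
    pct_gaps_lt_60s = if (length(gaps)) 100 * mean(gaps < 60) else 100,
    max_gap_s = if (length(gaps)) max(gaps) else 0L,
    min_gap_s = if (length(gaps)) min(gaps) else 0L
  )
}
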