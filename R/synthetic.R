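#' Configure a synthetic paired-monitoring cohort
#'
#' Generates the study conditions of a postoperative continuous-monitoring
#' validation: each patient has a latent mean-reverting AR(1) vital-sign
#' trajectory observed by a reference monitor (additive noise, occasional
#' invalid samples) and by a wearable (patient-specific device bias, additive
#' noise with a small contaminating artifact component, bursty quality
#' dropout from a two-state Markov chain, and a constant clock offset).
#'
#' Default effect sizes emulate a published wrist-worn PPG validation cohort:
#' 62 patients, recording lengths with median about 1.2 h (16 min to 10 h),
#' heart-rate bias -0.15 bpm with total difference SD 1.8 bpm,
#' respiratory-rate bias 0.17 rpm with total SD 2.6 rpm, wearable
#' availability about 94% (HR) and 34% (RR) with strong between-patient
#' heterogeneity, and gap-length geometry giving roughly 96% (HR) / 81%
#' (RR) of gaps under a minute. The artifact mixture makes the difference
#' distribution heavy-tailed, as wrist PPG errors are, so the
#' within-threshold percentages (about 98% within 5 bpm, 93% within 3 rpm)
#' are lower than a pure Gaussian with the same SD would give.
#'
#' @param n_patients number of patients (default 62).
#' @param duration_s `NULL` (default) to draw per-patient recording lengths
#'   from a truncated lognormal with median 4320 s on `[960, 36000]` s; a
#'   scalar for a fixed duration; or `c(min, max)` for an integer-uniform
#'   draw.
#' @param lag_s wearable clock offset in seconds: scalar (fixed for all
#'   patients) or `c(min, max)` for a per-patient integer-uniform draw
#'   (default `c(-60, 60)`).
#' @param vitals which vitals to generate, subset of `c("HR", "RR")`.
#' @param rr_missing_rate probability a patient lacks a reference
#'   respiratory-rate channel (no usable capnography; default 8/62).
#' @param hr,rr named lists overriding per-vital parameters; see Details.
#' @param arrhythmia_burst optional `c(start_s, end_s)` window (recording-
#'   relative) in which wearable quality is forced below 4, mimicking an
#'   arrhythmia-detector lockout.
#' @param seed master seed; per-patient substreams are derived
#'   deterministically from `(seed, patient_index)`, so any patient can be
#'   regenerated in isolation.
#'
#' @details Per-vital parameters (defaults for HR / RR):
#' \describe{
#'   \item{baseline_mean, baseline_sd}{population baseline, 75/10 bpm and
#'     14/3 rpm.}
#'   \item{ar_coef, ar_noise_sd}{AR(1) coefficient and innovation SD of the
#'     latent trajectory at 1 Hz: 0.99 and 1.0 bpm / 0.3 rpm (stationary
#'     within-patient SD about 7 bpm / 2.1 rpm, decorrelation time about
#'     100 s — slow enough to be physiological, fast enough that
#'     cross-correlation synchronization is identifiable).}
#'   \item{bias_mean, bias_between_sd}{device bias mean and between-patient
#'     SD: -0.15/0.8 bpm, 0.17/0.8 rpm.}
#'   \item{wearable_noise_sd, artifact_rate, artifact_sd}{wearable error is
#'     a contaminated normal: SD `wearable_noise_sd` with probability
#'     `1 - artifact_rate`, SD `artifact_sd` otherwise; 0.93/0.03/6.5 bpm,
#'     0.81/0.06/9 rpm.}
#'   \item{reference_noise_sd}{reference monitor noise SD: 0.7 bpm, 0.8 rpm.}
#'   \item{dropout_on_rate, dropout_off_rate}{per-second transition
#'     probabilities good-to-bad and bad-to-good of the wearable quality
#'     chain: 0.0032/0.05 (HR), 0.054/0.0278 (RR).}
#'   \item{availability_shape}{optional `c(alpha, beta)` of a Beta
#'     distribution for per-patient good-state occupancy; when set (default
#'     `c(14, 1)` HR, `c(0.9, 2.1)` RR) the on-rate is re-derived per
#'     patient as `off * (1 - p_i) / p_i`, reproducing the wide
#'     between-patient spread of real coverage; `NULL` uses the fixed
#'     on-rate.}
#'   \item{reference_invalid_rate}{per-sample probability the reference
#'     sample is invalid (flag 0): 0.02 (ECG-derived HR), 0.26
#'     (capnography RR).}
#'   \item{threshold}{clinical acceptability threshold: 5 bpm, 3 rpm.}
#' }
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_patients = 62, duration_s = NULL,
                                    lag_s = c(-60, 60), vitals = c("HR", "RR"),
                                    rr_missing_rate = 8 / 62,
                                    hr = list(), rr = list(),
                                    arrhythmia_burst = NULL, seed = 1L) {
  hr_defaults <- list(
    baseline_mean = 75, baseline_sd = 10, ar_coef = 0.99, ar_noise_sd = 1.0,
    bias_mean = -0.15, bias_between_sd = 0.8,
    wearable_noise_sd = 0.93, artifact_rate = 0.03, artifact_sd = 6.5,
    reference_noise_sd = 0.7,
    dropout_on_rate = 0.0032, dropout_off_rate = 0.05,
    availability_shape = c(14, 1),
    reference_invalid_rate = 0.02, threshold = 5
  )
  rr_defaults <- list(
    baseline_mean = 14, baseline_sd = 3, ar_coef = 0.99, ar_noise_sd = 0.3,
    bias_mean = 0.17, bias_between_sd = 0.8,
    wearable_noise_sd = 0.81, artifact_rate = 0.06, artifact_sd = 9,
    reference_noise_sd = 0.8,
    dropout_on_rate = 0.054, dropout_off_rate = 0.0278,
    availability_shape = c(0.9, 2.1),
    reference_invalid_rate = 0.26, threshold = 3
  )
  cfg <- list(
    n_patients = n_patients, duration_s = duration_s, lag_s = lag_s,
    vitals = match.arg(vitals, several.ok = TRUE),
    rr_missing_rate = rr_missing_rate,
    hr = utils::modifyList(hr_defaults, hr),
    rr = utils::modifyList(rr_defaults, rr),
    arrhythmia_burst = arrhythmia_burst,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "synthetic_cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, field) if (!isTRUE(all(ok))) bad <<- c(bad, field)
  chk(cfg$n_patients >= 1, "n_patients")
  if (!is.null(cfg$duration_s)) {
    chk(length(cfg$duration_s) %in% 1:2 && all(cfg$duration_s >= 1), "duration_s")
  }
  chk(length(cfg$lag_s) %in% 1:2, "lag_s")
  chk(cfg$rr_missing_rate >= 0 && cfg$rr_missing_rate <= 1, "rr_missing_rate")
  for (v in c("hr", "rr")) {
    p <- cfg[[v]]
    chk(p$baseline_mean > 0, paste0(v, "$baseline_mean"))
    for (f in c("baseline_sd", "ar_noise_sd", "bias_between_sd",
                "wearable_noise_sd", "artifact_sd", "reference_noise_sd")) {
      chk(p[[f]] >= 0, paste0(v, "$", f))
    }
    chk(p$ar_coef >= 0 && p$ar_coef < 1, paste0(v, "$ar_coef"))
    for (f in c("artifact_rate", "dropout_on_rate", "dropout_off_rate",
                "reference_invalid_rate")) {
      chk(p[[f]] >= 0 && p[[f]] <= 1, paste0(v, "$", f))
    }
    if (!is.null(p$availability_shape)) {
      chk(length(p$availability_shape) == 2 && all(p$availability_shape > 0),
          paste0(v, "$availability_shape"))
    }
    chk(p$threshold > 0, paste0(v, "$threshold"))
  }
  if (length(bad)) {
    stop("invalid synthetic cohort config; offending field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

# evaluate expr under a private RNG stream, restoring the caller's state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

patient_substream_seed <- function(seed, patient_index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(patient_index) * 10007) %% 2147483647)
}

# alternating-run simulation of the two-state quality chain; returns logical
# good-state vector of length n
simulate_dropout_chain <- function(n, on_rate, off_rate) {
  p_good <- if (on_rate + off_rate > 0) off_rate / (on_rate + off_rate) else 1
  state <- stats::runif(1) < p_good
  out <- logical(n)
  i <- 1L
  while (i <= n) {
    leave <- if (state) on_rate else off_rate
    len <- if (leave <= 0) n - i + 1L else stats::rgeom(1, leave) + 1L
    j <- min(n, i + len - 1L)
    out[i:j] <- state
    i <- j + 1L
    state <- !state
  }
  out
}

draw_duration <- function(duration_s) {
  if (is.null(duration_s)) {
    ml <- log(4320); sl <- 0.9
    lo <- stats::plnorm(960, ml, sl); hi <- stats::plnorm(36000, ml, sl)
    return(as.integer(round(stats::qlnorm(stats::runif(1, lo, hi), ml, sl))))
  }
  if (length(duration_s) == 2L) {
    return(as.integer(round(stats::runif(1, duration_s[1], duration_s[2]))))
  }
  as.integer(duration_s)
}

#' Simulate one patient's paired recordings
#'
#' Fully reproducible from `(config$seed, patient_index)`; the global RNG
#' state of the caller is left untouched.
#'
#' @param config a [synthetic_cohort_config()].
#' @param patient_index 1-based patient index within the cohort.
#' @return A [patient_recording()] carrying a `truth_info` attribute (list
#'   with `duration_s`, `lag_s`, `delta_hr`, `delta_rr`,
#'   `has_rr_reference`) used by the cohort manifest and oracle tests.
#' @export
simulate_patient <- function(config, patient_index) {
  validate_cohort_config(config)
  with_rng(patient_substream_seed(config$seed, patient_index), {
    pid <- sprintf("p%03d", patient_index)
    dur <- draw_duration(config$duration_s)
    lag <- if (length(config$lag_s) == 2L) {
      as.integer(round(stats::runif(1, config$lag_s[1], config$lag_s[2])))
    } else as.integer(config$lag_s)
    delta <- list(
      HR = stats::rnorm(1, config$hr$bias_mean, config$hr$bias_between_sd),
      RR = stats::rnorm(1, config$rr$bias_mean, config$rr$bias_between_sd)
    )
    has_rr_ref <- stats::runif(1) >= config$rr_missing_rate

    slots <- list(patient_id = pid)
    for (vital in config$vitals) {
      p <- config[[tolower(vital)]]
      upper <- if (vital == "HR") 300 else 100
      clip <- function(x) pmin(pmax(x, 0.1), upper - 0.1)

      burn <- 500L
      pad_lo <- max(0L, lag)
      pad_hi <- max(0L, -lag)
      n_ext <- burn + pad_lo + dur + pad_hi
      baseline <- stats::rnorm(1, p$baseline_mean, p$baseline_sd)
      truth_ext <- baseline + as.numeric(stats::filter(
        stats::rnorm(n_ext, 0, p$ar_noise_sd), p$ar_coef, method = "recursive"))
      # truth at recording-time t (0-based) is truth_at(t)
      truth_at <- function(t) truth_ext[burn + pad_lo + t + 1L]

      t_grid <- 0:(dur - 1L)
      make_ref <- vital == "HR" || has_rr_ref
      if (make_ref) {
        ref_val <- clip(truth_at(t_grid) + stats::rnorm(dur, 0, p$reference_noise_sd))
        ref_q <- rep(4L, dur)
        invalid <- stats::runif(dur) < p$reference_invalid_rate
        ref_val[invalid] <- NA_real_
        ref_q[invalid] <- 0L
        slots[[paste0(tolower(vital), "_reference")]] <-
          vital_series(ref_val, ref_q, pid, "reference", vital, t0 = 0L)
      }

      noise <- stats::rnorm(dur, 0, p$wearable_noise_sd)
      art <- stats::runif(dur) < p$artifact_rate
      if (any(art)) noise[art] <- stats::rnorm(sum(art), 0, p$artifact_sd)
      wear_val <- clip(truth_at(t_grid - lag) + delta[[vital]] + noise)

      on_rate <- p$dropout_on_rate
      if (!is.null(p$availability_shape)) {
        p_i <- stats::rbeta(1, p$availability_shape[1], p$availability_shape[2])
        p_i <- min(max(p_i, 0.005), 0.998)
        on_rate <- p$dropout_off_rate * (1 - p_i) / p_i
        on_rate <- min(on_rate, 1)
      }
      good <- simulate_dropout_chain(dur, on_rate, p$dropout_off_rate)
      wear_q <- ifelse(good, 4L, sample(0:3, dur, replace = TRUE))
      if (!is.null(config$arrhythmia_burst)) {
        w <- t_grid >= config$arrhythmia_burst[1] & t_grid <= config$arrhythmia_burst[2]
        if (any(w)) wear_q[w] <- sample(1:3, sum(w), replace = TRUE)
      }
      wear_val[wear_q == 0L] <- NA_real_
      slots[[paste0(tolower(vital), "_wearable")]] <-
        vital_series(wear_val, wear_q, pid, "wearable", vital, t0 = 0L)
    }

    rec <- do.call(patient_recording, slots)
    attr(rec, "truth_info") <- list(
      duration_s = dur, lag_s = lag,
      delta_hr = delta$HR, delta_rr = delta$RR,
      has_rr_reference = has_rr_ref && "RR" %in% config$vitals
    )
    rec
  })
}

#' Simulate a full paired cohort
#'
#' @param config a [synthetic_cohort_config()].
#' @return List with `recordings` (named list of [patient_recording]
#'   objects) and `manifest` (data frame `patient_id`, `duration_s`,
#'   `lag_s`, `delta_hr`, `delta_rr`, `has_rr_reference`) exposing the true
#'   per-patient bias and lag for oracle tests.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  recs <- lapply(seq_len(config$n_patients), function(i) simulate_patient(config, i))
  names(recs) <- vapply(recs, `[[`, character(1), "patient_id")
  manifest <- do.call(rbind, lapply(recs, function(r) {
    info <- attr(r, "truth_info")
    data.frame(patient_id = r$patient_id, duration_s = info$duration_s,
               lag_s = info$lag_s, delta_hr = info$delta_hr,
               delta_rr = info$delta_rr, has_rr_reference = info$has_rr_reference)
  }))
  rownames(manifest) <- NULL
  list(recordings = recs, manifest = manifest)
}

#' Closed-form agreement expectations for a synthetic configuration
#'
#' When the clock offset is corrected, the latent trajectory cancels in the
#' wearable-minus-reference difference, leaving
#' `d = delta_i + eps_wear - eps_ref`, so the expected bias is the
#' configured bias mean and the expected SD of a single difference is
#' `sqrt(bias_between_sd^2 + wearable_noise_var + reference_noise_sd^2)`
#' with the contaminated-normal wearable variance
#' `(1 - artifact_rate) * wearable_noise_sd^2 + artifact_rate * artifact_sd^2`.
#'
#' @param config a [synthetic_cohort_config()].
#' @param vital `"HR"` or `"RR"`.
#' @param z limit multiplier (default 1.96).
#' @return List with `bias`, `sd_total`, `loa_lower`, `loa_upper`.
#' @export
theoretical_agreement <- function(config, vital = "HR", z = 1.96) {
  p <- config[[tolower(vital)]]
  w_var <- (1 - p$artifact_rate) * p$wearable_noise_sd^2 +
    p$artifact_rate * p$artifact_sd^2
  sd_total <- sqrt(p$bias_between_sd^2 + w_var + p$reference_noise_sd^2)
  list(
    bias = p$bias_mean,
    sd_total = sd_total,
    loa_lower = p$bias_mean - z * sd_total,
    loa_upper = p$bias_mean + z * sd_total
  )
}
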