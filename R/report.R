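#' Format a count as a display percentage
#'
#' Display conventions for validation tables: availability percentages are
#' printed as whole numbers, error-grid zone percentages with one decimal,
#' and composite rows (e.g. zone A+B) collapse to `"100"` once the value
#' reaches 99.95. Rounding is half-up, matching how the tables are printed;
#' display rounding never feeds back into computation.
#'
#' @param count,total nonnegative counts, `total > 0`.
#' @param style `"availability"` (integer), `"zone"` (one decimal) or
#'   `"composite"` (one decimal, rendered `"100"` at or above 99.95).
#' @return Character scalar.
#' @examples
#' format_percent(492987, 526833, "availability")  # "94"
#' format_percent(483716, 484096, "zone")          # "99.9"
#' format_percent(484085, 484096, "composite")     # "100"
#' @export
format_percent <- function(count, total, style = c("availability", "zone", "composite")) {
  style <- match.arg(style)
  if (!is.finite(total) || total <= 0) stop("total must be positive", call. = FALSE)
  pct <- 100 * count / total
  round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits
  if (style == "availability") {
    sprintf("%d", as.integer(round_half_up(pct, 0)))
  } else if (style == "composite" && pct >= 99.95) {
    "100"
  } else {
    sprintf("%.1f", round_half_up(pct, 1))
  }
}

#' Run the full wearable-versus-reference validation pipeline
#'
#' Composes the whole analysis per vital: exclusion of patients with short
#' or absent reference recordings, heart-rate cross-correlation clock
#' synchronization (the respiratory channel reuses its patient's heart-rate
#' lag), dual quality filtering, pairing, coverage/gap analytics,
#' repeated-measures Bland-Altman agreement with MOVER intervals, and
#' error-grid classification. Per-patient failures (e.g. unsynchronizable
#' signals) are logged and skipped; the run fails only if no patient
#' survives.
#'
#' @param cohort list of [patient_recording] objects (e.g.
#'   `simulate_cohort(cfg)$recordings` or [read_cohort_csv()] output).
#' @param vitals vitals to analyze, subset of `c("HR", "RR")`.
#' @param min_quality wearable quality cutoff (default 4).
#' @param min_minutes minimum reference recording length in minutes
#'   (default 15).
#' @param max_lag_s half-width of the synchronization search window
#'   (default 300).
#' @param thresholds named numeric, within-threshold tolerances per vital
#'   (default 5 bpm HR, 3 rpm RR).
#' @param grid_configs named list of [error_grid_config()] per vital;
#'   defaults to the standard early-warning-score bands.
#' @param lag_overrides optional named numeric vector `patient_id -> lag`
#'   replacing the estimated lag (the reproducible stand-in for manual
#'   resynchronization after visual inspection).
#' @param z,alpha limit multiplier and MOVER error rate.
#' @return A `validation_report`: list with one block per vital (each with
#'   `availability`, `coverage`, `agreement`, `error_grid`,
#'   `per_patient` coverage/lag table), plus `exclusions` and `failures`
#'   data frames.
#' @export
run_validation <- function(cohort, vitals = c("HR", "RR"), min_quality = 4,
                           min_minutes = 15, max_lag_s = 300,
                           thresholds = c(HR = 5, RR = 3),
                           grid_configs = NULL, lag_overrides = NULL,
                           z = 1.96, alpha = 0.05) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  if (is.null(grid_configs)) {
    grid_configs <- list(HR = error_grid_config("HR"), RR = error_grid_config("RR"))
  }
  excl <- exclude_short_recordings(cohort, min_minutes = min_minutes)
  by_id <- setNames(cohort, vapply(cohort, `[[`, character(1), "patient_id"))

  # one lag per patient, estimated on HR (or overridden)
  lags <- list()
  failures <- list()
  fail <- function(patient_id, vital, stage, message) {
    failures[[length(failures) + 1L]] <<- data.frame(
      patient_id = patient_id, vital = vital, stage = stage, message = message)
  }
  hr_eligible <- excl$eligible$HR
  for (pid in union(excl$eligible$HR, excl$eligible$RR)) {
    rec <- by_id[[pid]]
    if (!is.null(lag_overrides) && pid %in% names(lag_overrides)) {
      lags[[pid]] <- as.integer(lag_overrides[[pid]])
      next
    }
    if (is.null(rec$hr_wearable) || is.null(rec$hr_reference)) {
      fail(pid, "HR", "synchronize", "missing HR stream for lag estimation")
      next
    }
    lags[[pid]] <- tryCatch(
      estimate_lag(rec$hr_wearable, rec$hr_reference, max_lag_s = max_lag_s),
      error = function(e) {
        fail(pid, "HR", "synchronize", conditionMessage(e))
        NULL
      }
    )
  }

  report <- list()
  for (vital in vitals) {
    slot_w <- paste0(tolower(vital), "_wearable")
    slot_r <- paste0(tolower(vital), "_reference")
    pair_list <- list()
    coverages <- list()
    per_patient <- list()
    counts <- c(n_overlap = 0, n_good_wearable = 0, n_good_reference = 0, n_both = 0)
    for (pid in excl$eligible[[vital]]) {
      rec <- by_id[[pid]]
      lag <- lags[[pid]]
      if (is.null(lag)) next  # synchronization already logged as failure
      if (is.null(rec[[slot_w]])) {
        fail(pid, vital, "pair", "missing wearable stream")
        next
      }
      res <- tryCatch({
        aligned <- apply_lag(rec[[slot_w]], rec[[slot_r]], lag, max_lag_s = max_lag_s)
        pp <- make_pairs(aligned, min_quality = min_quality)
        cov <- coverage_and_gaps(quality_mask(aligned$wearable, min_quality))
        list(pp = pp, cov = cov)
      }, error = function(e) {
        fail(pid, vital, "pair", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      pp <- res$pp
      counts <- counts + unlist(pp$counts)
      coverages[[pid]] <- res$cov
      if (nrow(pp$pairs)) {
        pair_list[[pid]] <- cbind(patient_id = pid, pp$pairs)
      }
      per_patient[[pid]] <- data.frame(
        patient_id = pid, vital = vital, lag_s = lag,
        n_overlap = pp$counts$n_overlap, n_both = pp$counts$n_both,
        pct_good = res$cov$pct_good, max_gap_s = res$cov$max_gap_s)
    }
    if (!length(pair_list)) {
      if (vital %in% vitals && length(excl$eligible[[vital]])) {
        stop("no patient survived the ", vital, " pipeline", call. = FALSE)
      }
      next
    }
    pairs <- do.call(rbind, pair_list)
    rownames(pairs) <- NULL
    agreement <- agreement_analysis(pairs, vital = vital,
                                    threshold = thresholds[[vital]],
                                    z = z, alpha = alpha)
    grid <- grid_summary(pairs, grid_configs[[vital]])
    per_patient_df <- do.call(rbind, per_patient)
    rownames(per_patient_df) <- NULL
    report[[vital]] <- list(
      vital = vital,
      availability = list(
        n_patients = length(coverages),
        n_measurements = unname(counts["n_overlap"]),
        n_good_wearable = unname(counts["n_good_wearable"]),
        n_good_reference = unname(counts["n_good_reference"]),
        n_both = unname(counts["n_both"])
      ),
      coverage = cohort_coverage_summary(coverages),
      agreement = agreement,
      error_grid = grid,
      per_patient = per_patient_df,
      pairs = pairs
    )
  }
  if (!length(report)) stop("no patient survived the pipeline", call. = FALSE)
  structure(
    list(
      vitals = report,
      exclusions = excl$exclusions,
      failures = if (length(failures)) do.call(rbind, failures) else
        data.frame(patient_id = character(), vital = character(),
                   stage = character(), message = character())
    ),
    class = "validation_report"
  )
}

report_block_json <- function(b) {
  av <- b$availability
  ag <- b$agreement
  eg <- b$error_grid
  list(
    vital = b$vital,
    availability = list(
      n_patients = av$n_patients,
      n_measurements = av$n_measurements,
      good_wearable = list(n = av$n_good_wearable,
                           pct = as.numeric(format_percent(av$n_good_wearable, av$n_measurements))),
      good_reference = list(n = av$n_good_reference,
                            pct = as.numeric(format_percent(av$n_good_reference, av$n_measurements))),
      both_good = list(n = av$n_both,
                       pct = as.numeric(format_percent(av$n_both, av$n_measurements)))
    ),
    coverage = list(
      median_pct_good = b$coverage$median_pct_good,
      iqr_pct_good = b$coverage$iqr_pct_good,
      pct_gaps_lt_60s = b$coverage$pct_gaps_lt_60s,
      max_gap_s = b$coverage$max_gap_s
    ),
    bland_altman = list(
      n_patients = ag$n_patients, n_pairs = ag$n_pairs,
      pearson_r = ag$pearson_r,
      bias = ag$bias, sd_total = ag$sd_total,
      sd_between = ag$sd_between, sd_within = ag$sd_within,
      loa_lower = ag$loa_lower, ci_loa_lower = unname(ag$ci_loa_lower),
      loa_upper = ag$loa_upper, ci_loa_upper = unname(ag$ci_loa_upper),
      threshold = ag$threshold, pct_within_threshold = ag$pct_within_threshold
    ),
    error_grid = list(
      n_pairs = eg$n_pairs,
      counts = as.list(eg$counts),
      pct = lapply(names(eg$counts), function(z) as.numeric(
        format_percent(eg$counts[[z]], eg$n_pairs,
                       style = if (z == "AB") "composite" else "zone"))) |>
        stats::setNames(names(eg$counts)),
      d_breakdown = as.list(eg$d_breakdown)
    )
  )
}

#' Write a validation report to disk
#'
#' Emits `report.json` (the machine-readable report), `table2.csv` (a
#' rendered summary table), `coverage_per_patient.csv`, and plot-ready
#' `ba_points_<vital>.csv` (t, ref, wear, diff, mean) and
#' `grid_points_<vital>.csv` (ref, wear, zone) files. Outputs contain no
#' timestamps, so identical inputs give byte-identical files.
#'
#' @param report a `validation_report` from [run_validation()].
#' @param dir output directory, created if needed.
#' @param points whether to write the per-second point files (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir, points = TRUE) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- lapply(report$vitals, report_block_json)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rows <- list()
  for (b in report$vitals) {
    av <- b$availability; ag <- b$agreement; eg <- b$error_grid
    cell <- function(n, total, style) sprintf("%d (%s)", n, format_percent(n, total, style))
    rows[[b$vital]] <- c(
      `Patients, n` = av$n_patients,
      `Measurements, n` = av$n_measurements,
      `Good-quality wearable, n (%)` = cell(av$n_good_wearable, av$n_measurements, "availability"),
      `Good-quality reference, n (%)` = cell(av$n_good_reference, av$n_measurements, "availability"),
      `Both good quality, n (%)` = cell(av$n_both, av$n_measurements, "availability"),
      `Pearson r` = sprintf("%.2f", ag$pearson_r),
      `Bias, mean (SD)` = sprintf("%.2f (%.1f)", ag$bias, ag$sd_total),
      `Lower LoA (95% CI)` = sprintf("%.2f (%.2f to %.2f)", ag$loa_lower,
                                     ag$ci_loa_lower[1], ag$ci_loa_lower[2]),
      `Upper LoA (95% CI)` = sprintf("%.2f (%.2f to %.2f)", ag$loa_upper,
                                     ag$ci_loa_upper[1], ag$ci_loa_upper[2]),
      `Within threshold, %` = format_percent(ag$pct_within_threshold, 100, "availability"),
      `Zone A, n (%)` = cell(eg$counts[["A"]], eg$n_pairs, "zone"),
      `Zone B, n (%)` = cell(eg$counts[["B"]], eg$n_pairs, "zone"),
      `Zone C, n (%)` = cell(eg$counts[["C"]], eg$n_pairs, "zone"),
      `Zone D, n (%)` = cell(eg$counts[["D"]], eg$n_pairs, "zone"),
      `Zone E, n (%)` = cell(eg$counts[["E"]], eg$n_pairs, "zone"),
      `Zone A+B, n (%)` = cell(eg$counts[["AB"]], eg$n_pairs, "composite")
    )
  }
  tab <- data.frame(row = names(rows[[1L]]),
                    do.call(cbind, rows), check.names = FALSE)
  names(tab) <- c("quantity", names(rows))
  utils::write.table(tab, file.path(dir, "table2.csv"), sep = ",",
                     row.names = FALSE, qmethod = "double")

  cov <- do.call(rbind, lapply(report$vitals, function(b) b$per_patient))
  utils::write.table(cov, file.path(dir, "coverage_per_patient.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  if (points) {
    for (b in report$vitals) {
      p <- b$pairs
      ba <- data.frame(t_s = p$t_s, ref = p$ref, wear = p$wear,
                       diff = p$wear - p$ref, mean = (p$wear + p$ref) / 2)
      utils::write.table(ba, file.path(dir, sprintf("ba_points_%s.csv", b$vital)),
                         sep = ",", row.names = FALSE, quote = FALSE)
      gp <- data.frame(ref = p$ref, wear = p$wear, zone = b$error_grid$zones)
      utils::write.table(gp, file.path(dir, sprintf("grid_points_%s.csv", b$vital)),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @export
print.validation_report <- function(x, ...) {
  for (b in x$vitals) {
    cat(sprintf("== %s ==\n", b$vital))
    av <- b$availability
    cat(sprintf("  patients %d, measurements %d; good wearable %d (%s%%), good reference %d (%s%%), both %d (%s%%)\n",
                av$n_patients, av$n_measurements,
                av$n_good_wearable, format_percent(av$n_good_wearable, av$n_measurements),
                av$n_good_reference, format_percent(av$n_good_reference, av$n_measurements),
                av$n_both, format_percent(av$n_both, av$n_measurements)))
    cat(sprintf("  coverage median %.0f%% (IQR %.0f-%.0f%%); %.0f%% of gaps < 60 s\n",
                b$coverage$median_pct_good, b$coverage$iqr_pct_good[1],
                b$coverage$iqr_pct_good[2], b$coverage$pct_gaps_lt_60s))
    print(b$agreement)
    print(b$error_grid)
  }
  if (nrow(x$exclusions)) {
    cat(sprintf("%d exclusion(s); ", nrow(x$exclusions)))
  }
  if (nrow(x$failures)) {
    cat(sprintf("%d per-patient failure(s)", nrow(x$failures)))
  }
  cat("\n")
  invisible(x)
}
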