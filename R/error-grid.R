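#' Configure an error grid for a vital sign
#'
#' The Clarke error grid, originally drawn for blood glucose, classifies
#' paired (reference, measured) values by the clinical consequence of the
#' measurement error. For heart and respiratory rate the zone geometry is
#' re-expressed through early-warning-score style thresholds: a low
#' (bradycardia / bradypnea) cutoff, a high (tachycardia / tachypnea)
#' cutoff, and a relative tolerance around the reference.
#'
#' Defaults follow common Modified Early Warning Score bands — heart rate
#' low 50 / high 110 bpm, respiratory rate low 9 / high 21 rpm — but ward
#' protocols differ, so all four thresholds are configurable. The normal
#' band is half-open `[low, high)`: a value exactly at the high threshold
#' counts as tachy.
#'
#' @param vital `"HR"` or `"RR"`.
#' @param rel_tolerance relative error below which a pair is zone A
#'   (default 0.20).
#' @param low value below which the vital is brady; default 50 bpm (HR) or
#'   9 rpm (RR).
#' @param high value at or above which the vital is tachy; default 110 bpm
#'   (HR) or 21 rpm (RR).
#' @param treat_low,treat_high measured values beyond which treatment would
#'   be triggered; default equal to `low`/`high`.
#' @return An `error_grid_config` list.
#' @export
error_grid_config <- function(vital = c("HR", "RR"), rel_tolerance = 0.20,
                              low = NULL, high = NULL,
                              treat_low = low, treat_high = high) {
  vital <- match.arg(vital)
  if (is.null(low)) low <- if (vital == "HR") 50 else 9
  if (is.null(high)) high <- if (vital == "HR") 110 else 21
  if (is.null(treat_low)) treat_low <- low
  if (is.null(treat_high)) treat_high <- high
  if (!(rel_tolerance > 0 && rel_tolerance < 1)) {
    stop("rel_tolerance must lie in (0, 1)", call. = FALSE)
  }
  if (!(low < high)) stop("low threshold must be below high threshold", call. = FALSE)
  if (!(treat_low <= low)) stop("treat_low must be <= low", call. = FALSE)
  if (!(treat_high >= high)) stop("treat_high must be >= high", call. = FALSE)
  structure(
    list(vital = vital, rel_tolerance = rel_tolerance, low = low, high = high,
         treat_low = treat_low, treat_high = treat_high),
    class = "error_grid_config"
  )
}

#' Classify paired measurements into error-grid zones
#'
#' Zones, by decreasing clinical benignity, with first-match precedence
#' A > E > D > C > B:
#' \describe{
#'   \item{A}{measured value within `rel_tolerance` of the reference, or
#'     both values brady (a correctly identified bradycardia/bradypnea).}
#'   \item{E}{brady and tachy confused in either direction.}
#'   \item{D}{reference outside the normal band but the measured value
#'     inside it — a missed bradycardia/bradypnea or tachycardia/tachypnea.}
#'   \item{C}{reference normal but the measured value beyond a treatment
#'     threshold — would trigger unnecessary treatment.}
#'   \item{B}{benign residual: off by more than the tolerance but with no
#'     treatment consequence.}
#' }
#'
#' @param ref,wear positive numeric vectors (recycled to common length).
#' @param config an [error_grid_config()].
#' @return Character vector of zone labels `"A"`..`"E"`.
#' @export
classify_points <- function(ref, wear, config) {
  stopifnot(inherits(config, "error_grid_config"))
  n <- max(length(ref), length(wear))
  ref <- rep_len(as.numeric(ref), n)
  wear <- rep_len(as.numeric(wear), n)
  if (anyNA(ref) || anyNA(wear) || any(ref <= 0) || any(wear <= 0)) {
    stop("reference and measured values must be positive and non-missing",
         call. = FALSE)
  }
  lo <- config$low; hi <- config$high
  in_band <- function(x) x >= lo & x < hi
  cond_a <- abs(wear - ref) <= config$rel_tolerance * ref | (ref < lo & wear < lo)
  cond_e <- (ref < lo & wear >= hi) | (ref >= hi & wear < lo)
  cond_d <- !in_band(ref) & in_band(wear)
  cond_c <- in_band(ref) & (wear < config$treat_low | wear >= config$treat_high)
  ifelse(cond_a, "A",
         ifelse(cond_e, "E",
                ifelse(cond_d, "D",
                       ifelse(cond_c, "C", "B"))))
}

#' Summarize error-grid zone occupancy
#'
#' @param pairs a `paired_points` object from [make_pairs()], or a data
#'   frame with columns `ref` and `wear`.
#' @param config an [error_grid_config()].
#' @return An `error_grid_result`: list with `n_pairs`, `counts` (named
#'   A-E plus `AB`), `pct` (same names, raw percentages), `d_breakdown`
#'   (missed-low vs missed-high counts inside zone D) and `zones` (the
#'   per-pair labels).
#' @export
grid_summary <- function(pairs, config) {
  df <- if (inherits(pairs, "paired_points")) pairs$pairs else pairs
  if (is.null(df$ref) || is.null(df$wear) || nrow(df) == 0L) {
    stop("need at least one (ref, wear) pair", call. = FALSE)
  }
  zones <- classify_points(df$ref, df$wear, config)
  counts <- vapply(c("A", "B", "C", "D", "E"), function(z) sum(zones == z), integer(1))
  counts <- c(counts, AB = unname(counts["A"] + counts["B"]))
  is_d <- zones == "D"
  d_breakdown <- c(
    missed_low = sum(is_d & df$ref < config$low),
    missed_high = sum(is_d & df$ref >= config$high)
  )
  structure(
    list(
      vital = config$vital,
      n_pairs = nrow(df),
      counts = counts,
      pct = 100 * counts / nrow(df),
      d_breakdown = d_breakdown,
      zones = zones
    ),
    class = "error_grid_result"
  )
}

#' @export
print.error_grid_result <- function(x, ...) {
  cat(sprintf("<error_grid_result> %s, %d pairs\n", x$vital, x$n_pairs))
  for (z in c("A", "B", "C", "D", "E", "AB")) {
    cat(sprintf("  %-2s %9d (%s)\n", z, x$counts[[z]],
                format_percent(x$counts[[z]], x$n_pairs,
                               style = if (z == "AB") "composite" else "zone")))
  }
  invisible(x)
}
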