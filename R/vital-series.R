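#' Construct a regular 1 Hz vital-sign series
#'
#' A `vital_series` is one device's view of a single vital sign on a strict
#' 1 Hz grid: a value vector (with `NA` for missing seconds) and a parallel
#' per-sample quality vector. Wearable devices report a quality index from 0
#' (unusable) to 4 (high quality); reference monitors report a 0/4 validity
#' flag. By convention a missing value always carries quality 0, and quality
#' 0 always carries a missing value, so "missing" has a single encoding.
#'
#' @param values numeric vector; one sample per second, `NA` = missing.
#' @param quality integer vector in 0..4, same length as `values`.
#'   Entries at missing values are forced to 0.
#' @param patient_id opaque patient identifier string.
#' @param device `"wearable"` or `"reference"`.
#' @param vital `"HR"` (heart rate, bpm) or `"RR"` (respiratory rate, rpm).
#' @param t0 integer epoch/offset second of the first sample (0-based offsets
#'   within a recording; no wall-clock convention is imposed).
#'
#' @return An object of class `vital_series` with fields `patient_id`,
#'   `device`, `vital`, `unit` (`"bpm"` or `"rpm"`), `t0`, `values`,
#'   `quality`.
#'
#' @details Present heart-rate values must lie in (0, 300) bpm and
#'   respiratory-rate values in (0, 100) rpm; values outside these
#'   physiological ranges are rejected rather than silently clipped.
#'
#' @examples
#' s <- vital_series(c(72, 73, NA, 74), c(4, 4, 0, 3), "p01", "wearable", "HR")
#' series_times(s)
#' @export
vital_series <- function(values, quality, patient_id, device = c("wearable", "reference"),
                         vital = c("HR", "RR"), t0 = 0L) {
  device <- match.arg(device)
  vital <- match.arg(vital)
  values <- as.numeric(values)
  quality <- as.integer(quality)
  if (length(values) < 1L) {
    stop("empty input: a vital_series needs at least one sample", call. = FALSE)
  }
  if (length(values) != length(quality)) {
    stop("values and quality must have equal length", call. = FALSE)
  }
  if (anyNA(quality) || any(quality < 0L | quality > 4L)) {
    stop("quality entries must be integers in 0..4", call. = FALSE)
  }
  quality[is.na(values)] <- 0L
  values[quality == 0L] <- NA_real_
  upper <- if (vital == "HR") 300 else 100
  present <- values[!is.na(values)]
  if (length(present) && (any(present <= 0) || any(present >= upper))) {
    stop(sprintf("%s values must lie in (0, %g)", vital, upper), call. = FALSE)
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      device = device,
      vital = vital,
      unit = if (vital == "HR") "bpm" else "rpm",
      t0 = as.integer(t0),
      values = values,
      quality = quality
    ),
    class = "vital_series"
  )
}

#' @export
print.vital_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<vital_series> %s %s (%s), patient %s\n  %d samples at 1 Hz, t0 = %d, %.1f%% present, %.1f%% quality 4\n",
    x$device, x$vital, x$unit, x$patient_id, n, x$t0,
    100 * mean(!is.na(x$values)), 100 * mean(x$quality == 4L)
  ))
  invisible(x)
}

#' @export
length.vital_series <- function(x) length(x$values)

#' Grid timestamps of a series
#'
#' @param x a `vital_series`.
#' @return Integer vector of the sample timestamps (seconds), `t0 + 0:(n-1)`.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "vital_series"))
  x$t0 + seq_along(x$values) - 1L
}

#' Crop a series to a closed time window
#'
#' @param x a `vital_series`.
#' @param from,to first and last second to keep (inclusive, on the series
#'   grid).
#' @return The cropped `vital_series`.
#' @export
series_window <- function(x, from, to) {
  stopifnot(inherits(x, "vital_series"))
  tt <- series_times(x)
  keep <- tt >= from & tt <= to
  if (!any(keep)) stop("window does not intersect the series grid", call. = FALSE)
  out <- x
  out$t0 <- as.integer(tt[keep][1L])
  out$values <- x$values[keep]
  out$quality <- x$quality[keep]
  out
}

#' Bundle one patient's wearable and reference streams
#'
#' @param patient_id patient identifier shared by all member series.
#' @param hr_wearable,hr_reference,rr_wearable,rr_reference `vital_series`
#'   objects or `NULL`. A reference respiratory-rate channel is optional:
#'   some patients lack usable capnography.
#' @param unit_admitted `"PACU"`, `"ICU"` or `NA` (metadata only; no analysis
#'   in this package stratifies on it).
#' @return An object of class `patient_recording`.
#' @export
patient_recording <- function(patient_id, hr_wearable = NULL, hr_reference = NULL,
                              rr_wearable = NULL, rr_reference = NULL,
                              unit_admitted = NA_character_) {
  series <- list(
    hr_wearable = hr_wearable, hr_reference = hr_reference,
    rr_wearable = rr_wearable, rr_reference = rr_reference
  )
  for (nm in names(series)) {
    s <- series[[nm]]
    if (is.null(s)) next
    if (!inherits(s, "vital_series")) stop(nm, " is not a vital_series", call. = FALSE)
    if (s$patient_id != as.character(patient_id)) {
      stop("all series in a recording must share patient_id", call. = FALSE)
    }
  }
  if (!is.na(unit_admitted) && !unit_admitted %in% c("PACU", "ICU")) {
    stop("unit_admitted must be \"PACU\", \"ICU\" or NA", call. = FALSE)
  }
  structure(
    c(list(patient_id = as.character(patient_id)), series,
      list(unit_admitted = unit_admitted)),
    class = "patient_recording"
  )
}

#' @export
print.patient_recording <- function(x, ...) {
  have <- vapply(
    c("hr_wearable", "hr_reference", "rr_wearable", "rr_reference"),
    function(nm) !is.null(x[[nm]]), logical(1)
  )
  cat(sprintf(
    "<patient_recording> patient %s (%s): %s\n",
    x$patient_id,
    ifelse(is.na(x$unit_admitted), "unit unknown", x$unit_admitted),
    paste(names(have)[have], collapse = ", ")
  ))
  invisible(x)
}
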