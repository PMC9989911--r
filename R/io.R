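#' Read a per-patient vital-sign stream from delimited text
#'
#' Reads one `<patient>_<device>_<vital>.csv` file (comma- or tab-delimited,
#' header required) with timestamp, value and quality columns, and returns a
#' [vital_series] on a strict 1 Hz grid from the first to the last timestamp.
#' Seconds absent from the file become missing samples with quality 0;
#' duplicate timestamps are resolved by keeping the last occurrence.
#' Non-integer timestamps (sub-second or coarser-than-1-Hz sources) are
#' regularized through [regularize_1hz()].
#'
#' @param path path to the delimited text file.
#' @param schema named character vector mapping the roles `t`, `value`,
#'   `quality` to column names in the file header.
#' @param patient_id,device,vital series metadata; when `NULL` they are
#'   parsed from a `<patient>_<device>_<vital>` file name.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param hold_max_s forward-fill window passed to [regularize_1hz()] when
#'   the timestamps are not already a 1 Hz integer grid; the default 0
#'   performs no filling on plain 1 Hz files.
#' @return A [vital_series].
#' @export
read_vitals_csv <- function(path,
                            schema = c(t = "t_s", value = "value", quality = "quality"),
                            patient_id = NULL, device = NULL, vital = NULL,
                            sep = NULL, hold_max_s = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty input file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          blank.lines.skip = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty input file (header only): ", path, call. = FALSE)
  need <- unname(schema[c("t", "value", "quality")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  parse_num <- function(x, col) {
    x[!nzchar(x)] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("malformed row in %s: line %d, column %s (%s)",
                   path, bad[1L] + 1L, col, x[bad[1L]]), call. = FALSE)
    }
    out
  }
  ts <- parse_num(df[[schema[["t"]]]], schema[["t"]])
  val <- parse_num(df[[schema[["value"]]]], schema[["value"]])
  qual <- parse_num(df[[schema[["quality"]]]], schema[["quality"]])
  if (anyNA(ts)) {
    stop(sprintf("malformed row in %s: line %d has no timestamp",
                 path, which(is.na(ts))[1L] + 1L), call. = FALSE)
  }
  if (is.unsorted(ts)) {
    stop("timestamps must be nondecreasing in ", path, call. = FALSE)
  }
  qual[is.na(qual)] <- 0

  meta <- parse_vitals_filename(path)
  if (is.null(patient_id)) patient_id <- meta$patient_id
  if (is.null(device)) device <- meta$device
  if (is.null(vital)) vital <- meta$vital

  regularize_1hz(ts, val, qual, patient_id = patient_id, device = device,
                 vital = vital, hold_max_s = hold_max_s)
}

parse_vitals_filename <- function(path) {
  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  if (length(parts) < 3L) {
    stop("cannot infer metadata from file name ", basename(path),
         "; expected <patient>_<device>_<vital>.csv or explicit arguments",
         call. = FALSE)
  }
  n <- length(parts)
  list(
    patient_id = paste(parts[seq_len(n - 2L)], collapse = "_"),
    device = parts[n - 1L],
    vital = toupper(parts[n])
  )
}

#' Resample an irregular stream onto the common 1 Hz grid
#'
#' Maps timestamped samples onto integer seconds covering the first to last
#' observed timestamp. Duplicate integer timestamps keep the last occurrence;
#' several sub-second samples within one second are aggregated by the mean of
#' the present values (the minimum of their quality indices is kept, so one
#' poor constituent sample degrades the aggregate). Sources slower than 1 Hz
#' (e.g. a 0.1 Hz respiratory-rate channel) are forward-filled for up to
#' `hold_max_s` seconds past each observation; seconds beyond the hold window
#' stay missing.
#'
#' @param timestamps numeric seconds, nondecreasing.
#' @param values numeric samples (`NA` = missing).
#' @param quality integer 0..4 quality/validity per sample.
#' @param patient_id,device,vital metadata for the resulting series.
#' @param hold_max_s maximum forward-fill in seconds (default 10, one
#'   reporting interval of a 0.1 Hz channel).
#' @return A [vital_series] whose grid spacing is exactly 1 s and whose span
#'   covers `[floor(min(timestamps)), floor(max(timestamps))]`.
#' @export
regularize_1hz <- function(timestamps, values, quality,
                           patient_id = "unknown", device = "wearable",
                           vital = "HR", hold_max_s = 10) {
  if (length(timestamps) == 0L) stop("empty input: no samples to regularize", call. = FALSE)
  stopifnot(length(values) == length(timestamps), length(quality) == length(timestamps))
  if (is.unsorted(timestamps)) stop("timestamps must be nondecreasing", call. = FALSE)
  sec <- floor(timestamps)
  quality <- as.integer(round(quality))

  # exact duplicates of a full timestamp: last occurrence wins
  keep <- !duplicated(timestamps, fromLast = TRUE)
  timestamps <- timestamps[keep]; values <- values[keep]
  quality <- quality[keep]; sec <- sec[keep]

  # aggregate within each integer second: mean of present values, min quality
  agg_val <- tapply(values, sec, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  agg_q <- tapply(quality, sec, min)
  sec_u <- as.numeric(names(agg_val))

  t0 <- sec_u[1L]
  grid <- seq(t0, sec_u[length(sec_u)])
  vals <- rep(NA_real_, length(grid))
  qual <- rep(0L, length(grid))
  idx <- match(sec_u, grid)
  vals[idx] <- as.numeric(agg_val)
  qual[idx] <- as.integer(agg_q)
  qual[is.na(vals)] <- 0L

  if (hold_max_s > 0 && anyNA(vals)) {
    last_obs <- cummax(ifelse(!is.na(vals), seq_along(vals), 0L))
    fillable <- is.na(vals) & last_obs > 0L &
      (seq_along(vals) - last_obs) <= hold_max_s
    vals[fillable] <- vals[last_obs[fillable]]
    qual[fillable] <- qual[last_obs[fillable]]
  }

  vital_series(vals, qual, patient_id = patient_id, device = device,
               vital = vital, t0 = t0)
}

#' Write a series in the package's delimited-text dialect
#'
#' Columns `t_s,value,quality`; missing values are written as empty fields.
#' A write followed by [read_vitals_csv()] reproduces the series exactly.
#'
#' @param x a [vital_series].
#' @param path output path.
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "vital_series"))
  df <- data.frame(t_s = series_times(x), value = x$values, quality = x$quality)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a directory of per-patient stream files into recordings
#'
#' Expects files named `<patient>_<device>_<vital>.csv` as written by
#' [write_cohort_csv()]; any subset of the four streams may be present per
#' patient.
#'
#' @param dir input directory.
#' @param hold_max_s forward-fill window for coarse channels, see
#'   [read_vitals_csv()].
#' @return A named list of [patient_recording] objects.
#' @export
read_cohort_csv <- function(dir, hold_max_s = 0) {
  files <- list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) stop("no stream files found in ", dir, call. = FALSE)
  meta <- lapply(files, parse_vitals_filename)
  pats <- vapply(meta, `[[`, character(1), "patient_id")
  out <- list()
  for (p in unique(pats)) {
    slots <- list(patient_id = p)
    for (i in which(pats == p)) {
      s <- read_vitals_csv(files[i], hold_max_s = hold_max_s)
      slot <- paste0(tolower(s$vital), "_", s$device)
      slots[[slot]] <- s
    }
    out[[p]] <- do.call(patient_recording, slots)
  }
  out
}

#' Write a cohort of recordings as per-stream CSV files
#'
#' @param cohort list of [patient_recording] objects (or a list with a
#'   `recordings` element, as returned by [simulate_cohort()], in which case
#'   the manifest is written alongside as `manifest.csv`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  if (!is.null(cohort$recordings)) {
    manifest <- cohort$manifest
    cohort <- cohort$recordings
  }
  for (rec in cohort) {
    for (slot in c("hr_wearable", "hr_reference", "rr_wearable", "rr_reference")) {
      s <- rec[[slot]]
      if (is.null(s)) next
      fn <- sprintf("%s_%s_%s.csv", rec$patient_id, s$device, s$vital)
      write_vitals_csv(s, file.path(dir, fn))
    }
  }
  if (!is.null(manifest)) {
    utils::write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}
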