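#' Sensor CSV dialect
#'
#' The logger export format is configurable because vendors differ in column
#' naming, separators and decimal marks. The default dialect is the one used
#' by the package fixtures: comma separator, `.` decimal mark, a `date`
#' column (`YYYY-MM-DD`), a `time` column with hundredths (`HH:MM:SS.hh`),
#' and acceleration columns `X`, `Y`, `Z`.
#'
#' @param col_date,col_time,col_x,col_y,col_z Column names in the file.
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @param digits Decimal digits used when writing acceleration values.
#'
#' @return A list of class `csv_dialect`.
#' @export
csv_dialect <- function(col_date = "date", col_time = "time",
                        col_x = "X", col_y = "Y", col_z = "Z",
                        sep = ",", dec = ".", digits = 6) {
  structure(list(col_date = col_date, col_time = col_time,
                 col_x = col_x, col_y = col_y, col_z = col_z,
                 sep = sep, dec = dec, digits = digits),
            class = "csv_dialect")
}

parse_trace_time <- function(date, time) {
  as.POSIXct(paste(date, time), format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
}

#' Read a sensor log CSV
#'
#' Reads a logger export with per-row date, time-of-day (to hundredths of a
#' second) and X/Y/Z acceleration, reconstructing one timestamp per sample.
#' Rows must be in strictly increasing time order; the nominal rate is 5 Hz.
#'
#' @param path Path to the CSV file.
#' @param dialect A [csv_dialect()] describing the file layout.
#' @param hz Nominal sampling rate recorded on the returned trace.
#'
#' @return An unlabeled [accel_trace()].
#' @export
read_sensor_csv <- function(path, dialect = csv_dialect(), hz = 5) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           dec = dialect$dec, colClasses = "character",
                           check.names = FALSE)
  needed <- c(dialect$col_date, dialect$col_time,
              dialect$col_x, dialect$col_y, dialect$col_z)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("sensor CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- raw[[col]]
    if (dialect$dec != ".") v <- gsub(dialect$dec, ".", v, fixed = TRUE)
    suppressWarnings(as.numeric(v))
  }
  x <- num(dialect$col_x); y <- num(dialect$col_y); z <- num(dialect$col_z)
  tm <- parse_trace_time(raw[[dialect$col_date]], raw[[dialect$col_time]])
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(tm))
  if (length(bad) > 0) {
    # +1 for the header line so the number matches the file
    stop("malformed sensor CSV row at line ", bad[1] + 1, call. = FALSE)
  }
  if (nrow(raw) > 1) {
    nonmono <- which(diff(as.numeric(tm)) <= 0)
    if (length(nonmono) > 0) {
      stop("non-monotonic timestamps: sample index ", nonmono[1] + 1,
           " does not advance", call. = FALSE)
    }
  }
  accel_trace(tm, x, y, z, hz = hz)
}

#' Write a sensor log CSV
#'
#' Inverse of [read_sensor_csv()]: values round-trip to the dialect's printed
#' precision.
#'
#' @param trace An [accel_trace()].
#' @inheritParams read_sensor_csv
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(trace, path, dialect = csv_dialect()) {
  fmt <- function(v) formatC(v, digits = dialect$digits, format = "f",
                             decimal.mark = dialect$dec)
  df <- data.frame(format(trace$time, "%Y-%m-%d"),
                   format(trace$time, "%H:%M:%OS2"),
                   fmt(trace$x), fmt(trace$y), fmt(trace$z))
  names(df) <- c(dialect$col_date, dialect$col_time,
                 dialect$col_x, dialect$col_y, dialect$col_z)
  utils::write.table(df, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Observer annotation intervals
#'
#' Intervals are half-open `[start, end)`: a sample on a boundary belongs to
#' the later interval, so abutting intervals never double-label. Intervals
#' must not overlap.
#'
#' @param start,end `POSIXct` interval bounds, `start < end` rowwise.
#' @param posture,behavior Labels for every sample the interval covers;
#'   vocabulary values or [ambiguous_label()].
#'
#' @return A tibble of class `annotation_intervals`.
#' @export
annotation_intervals <- function(start, end, posture, behavior) {
  stopifnot(length(start) == length(end),
            length(posture) == length(end),
            length(behavior) == length(end))
  if (any(as.numeric(end) <= as.numeric(start))) {
    stop("every interval needs start < end", call. = FALSE)
  }
  check_labels(posture, posture_levels(), "posture")
  check_labels(behavior, behavior_levels(), "behavior")
  iv <- tibble::tibble(start = start, end = end,
                       posture = posture, behavior = behavior)
  iv <- iv[order(as.numeric(iv$start)), ]
  # half-open intervals may abut exactly; allow sub-sample fp noise
  if (nrow(iv) > 1 &&
      any(as.numeric(iv$start[-1]) <
            as.numeric(iv$end[-nrow(iv)]) - 1e-6)) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  structure(iv, class = c("annotation_intervals", class(iv)))
}

#' Read / write annotation intervals
#'
#' CSV columns `start,end,posture,behavior` with timestamps formatted
#' `YYYY-MM-DD HH:MM:SS.hh`.
#'
#' @param path File path.
#' @return [read_annotations()] returns an [annotation_intervals()] tibble.
#' @export
read_annotations <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  annotation_intervals(
    start = as.POSIXct(raw$start, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC"),
    end = as.POSIXct(raw$end, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC"),
    posture = raw$posture, behavior = raw$behavior)
}

#' @rdname read_annotations
#' @param intervals An [annotation_intervals()] tibble.
#' @export
write_annotations <- function(intervals, path) {
  df <- data.frame(start = format(intervals$start, "%Y-%m-%d %H:%M:%OS2"),
                   end = format(intervals$end, "%Y-%m-%d %H:%M:%OS2"),
                   posture = intervals$posture,
                   behavior = intervals$behavior)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach observer labels to a trace
#'
#' Each sample takes the posture/behavior of the interval covering it
#' (half-open convention); samples no interval covers are labeled
#' [ambiguous_label()], matching how uncovered and observer-flagged samples
#' are both later removed.
#'
#' @param trace An [accel_trace()].
#' @param intervals An [annotation_intervals()] tibble (non-overlapping).
#' @return The trace with `posture` and `behavior` columns filled.
#' @export
apply_annotations <- function(trace, intervals) {
  iv <- annotation_intervals(intervals$start, intervals$end,
                             intervals$posture, intervals$behavior)
  t_num <- as.numeric(trace$time)
  idx <- findInterval(t_num, as.numeric(iv$start))
  covered <- idx >= 1
  # half-open [start, end): a sample at the boundary is NOT covered; the
  # 1e-6 s guard keeps fp noise from leaking the boundary sample in
  covered[covered] <- t_num[covered] <
    as.numeric(iv$end)[idx[covered]] - 1e-6
  posture <- rep(ambiguous_label(), nrow(trace))
  behavior <- rep(ambiguous_label(), nrow(trace))
  posture[covered] <- iv$posture[idx[covered]]
  behavior[covered] <- iv$behavior[idx[covered]]
  trace$posture <- posture
  trace$behavior <- behavior
  trace
}

#' Remove non-univocal observations
#'
#' Drops every sample whose label for the requested mode is
#' [ambiguous_label()], preserving order, and reports the bookkeeping in the
#' layout of the study's removal table: counts removed/retained and the
#' equivalent minutes at the trace's sampling rate.
#'
#' @param trace A labeled [accel_trace()].
#' @param mode `"posture"` or `"behavior"`.
#' @return A list with elements `trace` (the filtered trace) and `report`
#'   (a one-row tibble: `n_total`, `n_removed`, `n_retained`,
#'   `minutes_removed`, `minutes_retained`).
#' @export
drop_ambiguous <- function(trace, mode = c("posture", "behavior")) {
  mode <- match.arg(mode)
  if (is.null(trace[[mode]])) {
    stop("trace has no '", mode, "' labels", call. = FALSE)
  }
  hz <- trace_hz(trace)
  keep <- trace[[mode]] != ambiguous_label()
  out <- trace[keep, ]
  attr(out, "hz") <- hz
  class(out) <- class(trace)
  report <- tibble::tibble(
    n_total = length(keep),
    n_removed = sum(!keep),
    n_retained = sum(keep),
    minutes_removed = sum(!keep) / hz / 60,
    minutes_retained = sum(keep) / hz / 60)
  list(trace = out, report = report)
}
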