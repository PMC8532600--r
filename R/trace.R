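#' @keywords internal
"_PACKAGE"

#' Label vocabularies
#'
#' The fixed ethogram: three postures (standing and the two sternal
#' recumbencies) and five behaviors. Samples an observer could not assign to
#' a single class carry the sentinel [ambiguous_label()].
#'
#' @return A character vector of valid labels.
#' @export
posture_levels <- function() c("S", "RSR", "LSR")

#' @rdname posture_levels
#' @export
behavior_levels <- function() {
  c("feeding", "moving", "resting", "ruminating", "standing_still")
}

#' @rdname posture_levels
#' @export
ambiguous_label <- function() "AMBIGUOUS"

# posture/behavior pairs the ethogram allows: recumbent cows only rest or
# ruminate; feeding, moving and standing still require standing; rumination
# is legal in every posture.
ethogram_allowed <- function(posture, behavior) {
  if (posture == "S") {
    behavior %in% c("feeding", "moving", "standing_still", "ruminating")
  } else {
    behavior %in% c("resting", "ruminating")
  }
}

#' Construct an acceleration trace
#'
#' A trace is a tibble with one row per 5 Hz sample: a timestamp with 0.01 s
#' resolution, the three acceleration axes in gravitational units (x vertical
#' when the cow stands, y horizontal fore-aft, z orthogonal to the left
#' flank), and optional per-sample posture/behavior labels.
#'
#' @param time `POSIXct` timestamps, strictly increasing.
#' @param x,y,z Numeric acceleration on each axis (g).
#' @param posture,behavior Optional character labels per sample; each value
#'   must be in the corresponding vocabulary or [ambiguous_label()].
#' @param hz Nominal sampling rate, stored as an attribute (default 5).
#'
#' @return A tibble of class `accel_trace`.
#' @export
accel_trace <- function(time, x, y, z, posture = NULL, behavior = NULL,
                        hz = 5) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (n > 1) {
    dt <- diff(as.numeric(time))
    bad <- which(dt <= 0)
    if (length(bad) > 0) {
      stop("timestamps not strictly increasing at sample index ", bad[1] + 1,
           call. = FALSE)
    }
  }
  tr <- tibble::tibble(time = time, x = as.numeric(x), y = as.numeric(y),
                       z = as.numeric(z))
  if (!is.null(posture)) {
    check_labels(posture, posture_levels(), "posture")
    tr$posture <- posture
  }
  if (!is.null(behavior)) {
    check_labels(behavior, behavior_levels(), "behavior")
    tr$behavior <- behavior
  }
  new_accel_trace(tr, hz = hz)
}

new_accel_trace <- function(df, hz = 5) {
  structure(df,
            class = c("accel_trace", class(tibble::as_tibble(df))),
            hz = hz)
}

check_labels <- function(labels, vocab, what) {
  ok <- labels %in% c(vocab, ambiguous_label())
  if (!all(ok)) {
    stop(sprintf("invalid %s label(s): %s", what,
                 paste(unique(labels[!ok]), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.accel_trace <- function(x, ...) {
  hz <- attr(x, "hz")
  cat(sprintf("<accel_trace: %d samples at %g Hz (%.1f min)>\n",
              nrow(x), hz, nrow(x) / hz / 60))
  NextMethod()
}

trace_hz <- function(trace) {
  hz <- attr(trace, "hz")
  if (is.null(hz)) 5 else hz
}
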