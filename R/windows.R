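#' Add the acceleration-magnitude channel
#'
#' `amag` is the Euclidean norm of the three axes, sample by sample:
#' `sqrt(x^2 + y^2 + z^2)`. A motionless sensor reads `amag ~ 1` g.
#'
#' @param trace An [accel_trace()].
#' @return The trace with an `amag` column appended.
#' @export
add_magnitude <- function(trace) {
  trace$amag <- sqrt(trace$x^2 + trace$y^2 + trace$z^2)
  trace
}

#' Number of candidate window positions
#'
#' Starts at sample 1 and advances by `stride` while a full window still
#' fits: `floor((n - window) / stride) + 1` positions for `n >= window`,
#' zero otherwise.
#'
#' @param n Stream length in samples.
#' @param window Window length in samples (default 40 = 8 s at 5 Hz).
#' @param stride Hop between window starts in samples (default 13).
#' @return Integer count.
#' @export
candidate_count <- function(n, window = 40, stride = 13) {
  if (n < window) return(0L)
  as.integer((n - window) %/% stride) + 1L
}

#' Segment a labeled stream into observation windows
#'
#' Slides a `window`-sample frame along the trace at `stride`-sample hops;
#' a candidate is retained only if all of its samples share one
#' non-ambiguous label for the requested mode. Mixed-label and ambiguous
#' windows are excluded, so every observation unit has a single posture or
#' behavior.
#'
#' @param trace A labeled [accel_trace()] (typically already passed through
#'   [drop_ambiguous()] for the same mode).
#' @param mode `"posture"` or `"behavior"`: which label stream governs
#'   retention.
#' @param window,stride Window length and hop, in samples.
#'
#' @return A list of class `window_set`: `trace`, `starts` (1-based start
#'   indices of retained windows), `labels` (the retained windows' labels),
#'   `mode`, `window`, `stride`, and a one-row `report` tibble with
#'   `candidates`, `retained`, `excluded`.
#' @export
segment_windows <- function(trace, mode = c("posture", "behavior"),
                            window = 40, stride = 13) {
  mode <- match.arg(mode)
  if (is.null(trace[[mode]])) {
    stop("trace has no '", mode, "' labels", call. = FALSE)
  }
  n <- nrow(trace)
  n_cand <- candidate_count(n, window, stride)
  if (n_cand == 0) {
    return(new_window_set(trace, integer(0), character(0), mode, window,
                          stride, candidates = 0L))
  }
  starts <- seq.int(1L, by = stride, length.out = n_cand)
  lab <- trace[[mode]]
  # run ids: a window is label-pure iff its first and last samples sit in
  # the same run of identical labels
  run_id <- cumsum(c(TRUE, lab[-1] != lab[-n]))
  pure <- run_id[starts] == run_id[starts + window - 1L]
  keep <- pure & lab[starts] != ambiguous_label()
  new_window_set(trace, starts[keep], lab[starts[keep]], mode, window,
                 stride, candidates = n_cand)
}

new_window_set <- function(trace, starts, labels, mode, window, stride,
                           candidates) {
  structure(list(
    trace = trace, starts = as.integer(starts), labels = labels,
    mode = mode, window = as.integer(window), stride = as.integer(stride),
    report = tibble::tibble(candidates = as.integer(candidates),
                            retained = length(starts),
                            excluded = as.integer(candidates) -
                              length(starts))),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set: %d/%d windows retained (%s mode, window %d, stride %d)>\n",
    x$report$retained, x$report$candidates, x$mode, x$window, x$stride))
  invisible(x)
}
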