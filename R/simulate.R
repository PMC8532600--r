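#' Behavior signal model
#'
#' Parametric description of the dynamic (non-gravitational) acceleration a
#' behavior adds on top of the posture's static gravity component:
#' an optional sinusoid (regular jaw cycles during rumination or feeding),
#' optional Poisson-timed impulses (steps, feed-pulling jerks), a slow
#' low-frequency drift when the behavior involves un-rhythmic body movement,
#' and white noise.
#'
#' @param behavior One of [behavior_levels()].
#' @param amplitude_g Dynamic acceleration scale (g), `>= 0`.
#' @param dominant_freq_hz Sinusoid frequency (Hz); 0 disables it. Must be
#'   below the Nyquist frequency of the 5 Hz sampling (2.5 Hz).
#' @param burst_rate_hz Mean impulse-event rate (Hz); 0 disables bursts.
#' @param noise_sd_g White-noise standard deviation (g), `>= 0` (0 gives
#'   the deterministic noise-free limit, useful for testing).
#'
#' @return A list of class `behavior_model`.
#' @export
behavior_model <- function(behavior, amplitude_g, dominant_freq_hz = 0,
                           burst_rate_hz = 0, noise_sd_g = 0.02) {
  stopifnot(behavior %in% behavior_levels(),
            amplitude_g >= 0,
            dominant_freq_hz >= 0, dominant_freq_hz < 2.5,
            burst_rate_hz >= 0,
            noise_sd_g >= 0)
  structure(list(behavior = behavior, amplitude_g = amplitude_g,
                 dominant_freq_hz = dominant_freq_hz,
                 burst_rate_hz = burst_rate_hz, noise_sd_g = noise_sd_g),
            class = "behavior_model")
}

#' Posture orientation model
#'
#' Static gravity direction seen by the flank sensor in a given posture,
#' plus a small per-bout orientation jitter (the harness never sits at
#' exactly the same angle twice).
#'
#' @param posture One of [posture_levels()].
#' @param gravity_unit_vector Length-3 unit vector in the sensor frame.
#' @param orientation_jitter_deg SD of the random per-bout tilt, degrees.
#'
#' @return A list of class `posture_model`.
#' @export
posture_model <- function(posture, gravity_unit_vector,
                          orientation_jitter_deg = 5) {
  stopifnot(posture %in% posture_levels(),
            length(gravity_unit_vector) == 3,
            orientation_jitter_deg >= 0)
  nrm <- sqrt(sum(gravity_unit_vector^2))
  if (abs(nrm - 1) > 1e-8) {
    stop("gravity_unit_vector must have unit norm", call. = FALSE)
  }
  structure(list(posture = posture,
                 gravity_unit_vector = as.numeric(gravity_unit_vector),
                 orientation_jitter_deg = orientation_jitter_deg),
            class = "posture_model")
}

#' Default simulator models
#'
#' Standing points the sensor's x axis down the gravity line; in sternal
#' recumbency the left flank faces the ground (LSR) or the sky (RSR), so
#' gravity loads the z axis with opposite signs. Behavior dynamics: resting
#' is near-still slow drift; rumination a regular 1 Hz jaw cycle; feeding a
#' 0.8 Hz chewing cycle with feed-pulling bursts; standing still is noise
#' only; moving is dominated by ~1 Hz step impulses (at least a step every
#' 10 s by definition, in practice about one per second when walking).
#' Scales are in g and are simulator choices, configurable per call.
#'
#' @return A named list of [posture_model()] / [behavior_model()] objects.
#' @export
default_posture_models <- function() {
  list(
    S   = posture_model("S",   c(-1, 0, 0)),
    RSR = posture_model("RSR", c(0, 0, 1)),
    LSR = posture_model("LSR", c(0, 0, -1)))
}

#' @rdname default_posture_models
#' @export
default_behavior_models <- function() {
  list(
    feeding        = behavior_model("feeding", 0.15, dominant_freq_hz = 0.8,
                                    burst_rate_hz = 0.3, noise_sd_g = 0.03),
    moving         = behavior_model("moving", 0.30, burst_rate_hz = 1.0,
                                    noise_sd_g = 0.05),
    resting        = behavior_model("resting", 0.01, noise_sd_g = 0.01),
    ruminating     = behavior_model("ruminating", 0.05,
                                    dominant_freq_hz = 1.0,
                                    noise_sd_g = 0.015),
    standing_still = behavior_model("standing_still", 0, noise_sd_g = 0.02))
}

# small random rotation of a unit vector: tilt by N(0, sd_deg) degrees
# around a random axis orthogonal to it, then renormalize.
jitter_direction <- function(v, sd_deg) {
  if (sd_deg <= 0) return(v)
  # random unit vector, orthogonalized against v
  r <- stats::rnorm(3)
  r <- r - sum(r * v) * v
  nr <- sqrt(sum(r^2))
  if (nr < 1e-12) return(v)
  r <- r / nr
  ang <- stats::rnorm(1, 0, sd_deg) * pi / 180
  out <- cos(ang) * v + sin(ang) * r
  out / sqrt(sum(out^2))
}

# moving-average smoothed standard noise, rescaled to unit sd
slow_drift <- function(n, hz) {
  k <- max(3, round(hz))
  e <- stats::rnorm(n + k - 1)
  s <- stats::filter(e, rep(1 / k, k), sides = 1)[k:(n + k - 1)]
  s <- as.numeric(s)
  sdev <- stats::sd(s)
  if (!is.finite(sdev) || sdev < 1e-12) rep(0, n) else s / sdev
}

# Poisson-timed impulses with a short decaying kernel, unit peak height
burst_train <- function(n, hz, rate_hz) {
  out <- rep(0, n)
  n_ev <- stats::rpois(1, rate_hz * n / hz)
  if (n_ev == 0) return(out)
  at <- sample.int(n, min(n_ev, n), replace = FALSE)
  kernel <- c(1, 0.5, 0.25)
  sgn <- sample(c(-1, 1), length(at), replace = TRUE)
  for (j in seq_along(at)) {
    idx <- at[j]:min(n, at[j] + length(kernel) - 1)
    out[idx] <- out[idx] + sgn[j] * kernel[seq_along(idx)]
  }
  out
}

# dynamic component of one bout, one column per axis; sinusoid rides mostly
# on y (fore-aft jaw/neck motion), bursts split between x and y, drift on
# all axes at reduced weight.
bout_dynamics <- function(model, n, hz) {
  t <- (seq_len(n) - 1) / hz
  d <- matrix(0, n, 3)
  if (model$dominant_freq_hz > 0 && model$amplitude_g > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    s <- model$amplitude_g * sin(2 * pi * model$dominant_freq_hz * t + phase)
    d[, 2] <- d[, 2] + s
    d[, 1] <- d[, 1] + 0.3 * model$amplitude_g *
      sin(2 * pi * model$dominant_freq_hz * t + phase + pi / 3)
  } else if (model$amplitude_g > 0) {
    for (ax in 1:3) {
      w <- if (ax == 2) 1 else 0.5
      d[, ax] <- d[, ax] + w * model$amplitude_g * slow_drift(n, hz)
    }
  }
  if (model$burst_rate_hz > 0 && model$amplitude_g > 0) {
    d[, 1] <- d[, 1] + model$amplitude_g * burst_train(n, hz, model$burst_rate_hz)
    d[, 2] <- d[, 2] + 0.7 * model$amplitude_g *
      burst_train(n, hz, model$burst_rate_hz)
  }
  d + matrix(stats::rnorm(3 * n, 0, model$noise_sd_g), n, 3)
}

#' Simulate one constant-label bout
#'
#' Generates `round(duration_s * hz)` samples of static gravity (the
#' posture's direction, tilted by one per-bout jitter draw) plus the
#' behavior's dynamic component. Deterministic given `seed`.
#'
#' @param posture A posture label or a [posture_model()].
#' @param behavior A behavior label or a [behavior_model()].
#' @param duration_s Bout duration in seconds (>= 8 s recommended, one
#'   window).
#' @param seed Optional integer seed.
#' @param hz Sampling rate (Hz).
#' @param start_time First-sample timestamp.
#'
#' @return A labeled [accel_trace()].
#' @export
simulate_bout <- function(posture, behavior, duration_s, seed = NULL,
                          hz = 5,
                          start_time = as.POSIXct("2019-04-01 11:00:00",
                                                  tz = "UTC")) {
  if (is.character(posture)) posture <- default_posture_models()[[posture]]
  if (is.character(behavior)) behavior <- default_behavior_models()[[behavior]]
  stopifnot(inherits(posture, "posture_model"),
            inherits(behavior, "behavior_model"),
            duration_s > 0)
  if (!ethogram_allowed(posture$posture, behavior$behavior)) {
    stop(sprintf("ethogram-inconsistent pair: %s while %s",
                 behavior$behavior, posture$posture), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * hz)
  g <- jitter_direction(posture$gravity_unit_vector,
                        posture$orientation_jitter_deg)
  acc <- bout_dynamics(behavior, n, hz) +
    matrix(g, n, 3, byrow = TRUE)
  tm <- start_time + (seq_len(n) - 1) / hz
  accel_trace(tm, acc[, 1], acc[, 2], acc[, 3],
              posture = rep(posture$posture, n),
              behavior = rep(behavior$behavior, n), hz = hz)
}

#' Session schedule
#'
#' An ordered bout list plus the fraction of samples to flag
#' [ambiguous_label()] around bout transitions (emulating spans the
#' observers could not assign to a single class, which the pipeline
#' removes).
#'
#' @param bouts A data frame with columns `posture`, `behavior`,
#'   `duration_s`; every pair must be ethogram-consistent.
#' @param ambiguous_fraction Target overall fraction of AMBIGUOUS samples,
#'   in `[0, 0.5)`; default 0.07, the removal rate observed in the
#'   motivating study.
#' @param seed Integer seed for the whole session.
#' @param hz Sampling rate (Hz).
#'
#' @return A list of class `session_schedule`.
#' @export
session_schedule <- function(bouts, ambiguous_fraction = 0.07, seed = NULL,
                             hz = 5) {
  bouts <- tibble::as_tibble(bouts)
  if (nrow(bouts) == 0) stop("schedule needs at least one bout", call. = FALSE)
  stopifnot(all(c("posture", "behavior", "duration_s") %in% names(bouts)),
            all(bouts$duration_s > 0),
            ambiguous_fraction >= 0, ambiguous_fraction < 0.5)
  check_labels(bouts$posture, posture_levels(), "posture")
  check_labels(bouts$behavior, behavior_levels(), "behavior")
  ok <- mapply(ethogram_allowed, bouts$posture, bouts$behavior)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("ethogram-inconsistent bout %d: %s while %s", bad,
                 bouts$behavior[bad], bouts$posture[bad]), call. = FALSE)
  }
  structure(list(bouts = bouts, ambiguous_fraction = ambiguous_fraction,
                 seed = seed, hz = hz),
            class = "session_schedule")
}

#' Default observation-session schedule
#'
#' A fixed 16-bout mixture whose time shares follow the posture/behavior
#' time budget reported for late-morning observation sessions: roughly 60%
#' standing / 40% lying, resting about 31% of time, feeding and moving about
#' 18% each, standing still about 20%, rumination about 12% split between
#' lying and standing.
#'
#' @param total_minutes Session length in minutes (default 90).
#' @param ambiguous_fraction,seed,hz Passed to [session_schedule()].
#' @return A `session_schedule`.
#' @export
default_schedule <- function(total_minutes = 90, ambiguous_fraction = 0.07,
                             seed = NULL, hz = 5) {
  frac <- c(0.060, 0.046, 0.068, 0.096, 0.052, 0.046, 0.060, 0.068,
            0.117, 0.030, 0.068, 0.036, 0.046, 0.096, 0.065, 0.046)
  posture <- c("S", "S", "S", "RSR", "RSR", "S", "S", "S",
               "LSR", "LSR", "S", "S", "S", "RSR", "S", "S")
  behavior <- c("feeding", "moving", "standing_still", "resting",
                "ruminating", "moving", "feeding", "standing_still",
                "resting", "ruminating", "standing_still", "ruminating",
                "moving", "resting", "feeding", "moving")
  session_schedule(
    tibble::tibble(posture = posture, behavior = behavior,
                   duration_s = frac * total_minutes * 60),
    ambiguous_fraction = ambiguous_fraction, seed = seed, hz = hz)
}

#' Simulate a full observation session
#'
#' Concatenates the scheduled bouts (each with its own derived seed), blends
#' the static orientation over ~1.5 s at posture changes, and flags samples
#' around every bout boundary as [ambiguous_label()] so that the overall
#' AMBIGUOUS share matches the schedule's `ambiguous_fraction`. The returned
#' ground-truth intervals cover exactly the non-ambiguous spans, so
#' [apply_annotations()] on them reproduces the trace labels.
#'
#' @param schedule A [session_schedule()].
#' @param start_time First-sample timestamp.
#'
#' @return A list: `trace` (labeled [accel_trace()]), `intervals`
#'   (ground-truth [annotation_intervals()]), and `bookkeeping` (per-bout
#'   sample counts plus `n_ambiguous`).
#' @export
simulate_session <- function(schedule,
                             start_time = as.POSIXct("2019-04-01 11:00:00",
                                                     tz = "UTC")) {
  stopifnot(inherits(schedule, "session_schedule"))
  bouts <- schedule$bouts
  hz <- schedule$hz
  if (!is.null(schedule$seed)) set.seed(schedule$seed)
  bout_seeds <- sample.int(.Machine$integer.max, nrow(bouts))

  n_bout <- round(bouts$duration_s * hz)
  traces <- vector("list", nrow(bouts))
  t0 <- start_time
  for (b in seq_len(nrow(bouts))) {
    traces[[b]] <- simulate_bout(bouts$posture[b], bouts$behavior[b],
                                 duration_s = n_bout[b] / hz,
                                 seed = bout_seeds[b], hz = hz,
                                 start_time = t0)
    t0 <- t0 + n_bout[b] / hz
  }
  tr <- do.call(rbind, lapply(traces, as.data.frame))
  tr <- new_accel_trace(tibble::as_tibble(tr), hz = hz)
  n_total <- nrow(tr)
  ends <- cumsum(n_bout)          # last sample index of each bout
  starts <- c(1, utils::head(ends, -1) + 1)

  # smooth the static component across posture changes: linear crossfade of
  # the two adjacent gravity estimates over ~1.5 s centered on the boundary
  if (nrow(bouts) > 1) {
    half <- max(1, round(0.75 * hz))
    for (b in seq_len(nrow(bouts) - 1)) {
      if (bouts$posture[b] == bouts$posture[b + 1]) next
      lo <- max(starts[b], ends[b] - half + 1)
      hi <- min(ends[b + 1], ends[b] + half)
      span <- lo:hi
      w <- seq(0, 1, length.out = length(span))
      g_prev <- colMeans(as.matrix(traces[[b]][, c("x", "y", "z")]))
      g_next <- colMeans(as.matrix(traces[[b + 1]][, c("x", "y", "z")]))
      for (ax in c("x", "y", "z")) {
        i <- match(ax, c("x", "y", "z"))
        base <- ifelse(span <= ends[b], g_prev[i], g_next[i])
        tr[[ax]][span] <- tr[[ax]][span] - base +
          ((1 - w) * g_prev[i] + w * g_next[i])
      }
    }
  }

  # AMBIGUOUS spans centered on the bout boundaries, sized to hit the
  # requested overall fraction
  ambig <- rep(FALSE, n_total)
  n_bound <- nrow(bouts) - 1
  n_ambig_target <- round(schedule$ambiguous_fraction * n_total)
  if (n_bound > 0 && n_ambig_target > 0) {
    per <- ceiling(n_ambig_target / n_bound)
    half <- ceiling(per / 2)
    for (b in seq_len(n_bound)) {
      lo <- max(1, ends[b] - half + 1)
      hi <- min(n_total, ends[b] + half)
      ambig[lo:hi] <- TRUE
    }
    # trim the tail span if rounding overshot the target (deterministic)
    overshoot <- sum(ambig) - n_ambig_target
    if (overshoot > 0) {
      ambig[utils::tail(which(ambig), overshoot)] <- FALSE
    }
  }
  tr$posture[ambig] <- ambiguous_label()
  tr$behavior[ambig] <- ambiguous_label()

  # ground truth: one interval per maximal run of identical non-ambiguous
  # label pairs (half-open, end = time of last sample + 1/hz)
  key <- ifelse(ambig, NA, paste(tr$posture, tr$behavior))
  r <- rle(ifelse(is.na(key), "<ambig>", key))
  run_end <- cumsum(r$lengths)
  run_start <- c(1, utils::head(run_end, -1) + 1)
  keep <- r$values != "<ambig>"
  intervals <- annotation_intervals(
    start = tr$time[run_start[keep]],
    end = tr$time[run_end[keep]] + 1 / hz,
    posture = tr$posture[run_start[keep]],
    behavior = tr$behavior[run_start[keep]])

  bookkeeping <- tibble::tibble(
    bout = seq_len(nrow(bouts)),
    posture = bouts$posture, behavior = bouts$behavior,
    n_samples = n_bout)
  list(trace = tr, intervals = intervals,
       bookkeeping = bookkeeping, n_ambiguous = sum(ambig))
}
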