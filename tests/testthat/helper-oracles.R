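# Brute-force loop oracles, written independently of the implementation:
# explicit running sums and element-wise loops, no vectorized shortcuts.

oracle_avg <- function(w) {
  s <- 0
  for (v in w) s <- s + v
  s / length(w)
}

oracle_sd <- function(w) {
  m <- oracle_avg(w)
  s <- 0
  for (v in w) s <- s + (v - m)^2
  sqrt(s / (length(w) - 1))
}

oracle_p2p <- function(w) {
  hi <- w[1]; lo <- w[1]
  for (v in w) {
    if (v > hi) hi <- v
    if (v < lo) lo <- v
  }
  hi - lo
}

oracle_rms <- function(w) {
  s <- 0
  for (v in w) s <- s + v^2
  sqrt(s / length(w))
}

# zero crossings after mean-centering; a sample exactly at zero keeps the
# sign of the last non-zero sample
oracle_zc <- function(w) {
  m <- oracle_avg(w)
  prev <- 0
  count <- 0
  for (v in w) {
    s <- sign(v - m)
    if (s != 0) {
      if (prev != 0 && s != prev) count <- count + 1
      prev <- s
    }
  }
  count
}

oracle_moment <- function(w, k) {
  m <- oracle_avg(w)
  s <- 0
  for (v in w) s <- s + (v - m)^k
  s / length(w)
}

oracle_skw <- function(w) oracle_moment(w, 3) / oracle_moment(w, 2)^1.5

oracle_kur <- function(w) oracle_moment(w, 4) / oracle_moment(w, 2)^2 - 3

oracle_cf <- function(w) {
  peak <- 0
  for (v in w) if (abs(v) > peak) peak <- abs(v)
  peak / oracle_rms(w)
}

oracle_vrms <- function(w) {
  running <- 0
  integ <- numeric(length(w))
  for (i in seq_along(w)) {
    running <- running + w[i]
    integ[i] <- running
  }
  oracle_rms(integ)
}

oracle_all_stats <- function(w) {
  c(avg = oracle_avg(w), sd = oracle_sd(w), zc = oracle_zc(w),
    p2p = oracle_p2p(w), rms = oracle_rms(w), kur = oracle_kur(w),
    skw = oracle_skw(w), cf = oracle_cf(w), Vrms = oracle_vrms(w))
}

# all minimal feature subsets whose removal leaves every remaining pair of
# columns below the cutoff (exhaustive search; only for tiny tables)
oracle_min_removals <- function(X, cutoff) {
  C <- abs(stats::cor(X))
  p <- ncol(C)
  valid <- list()
  for (size in 0:p) {
    combos <- utils::combn(p, size, simplify = FALSE)
    for (rm in combos) {
      keep <- setdiff(seq_len(p), rm)
      if (length(keep) < 2) {
        ok <- TRUE
      } else {
        sub <- C[keep, keep]
        diag(sub) <- 0
        ok <- max(sub) < cutoff
      }
      if (ok) valid[[length(valid) + 1]] <- colnames(C)[rm]
    }
    if (length(valid) > 0) return(valid)
  }
  valid
}

# constant-label trace helper: n samples of a fixed vector + labels
make_trace <- function(n, x = 0, y = 0, z = 1, posture = "S",
                       behavior = "standing_still", hz = 5,
                       t0 = as.POSIXct("2019-04-01 11:00:00", tz = "UTC")) {
  accel_trace(t0 + (seq_len(n) - 1) / hz,
              rep_len(x, n), rep_len(y, n), rep_len(z, n),
              posture = rep_len(posture, n),
              behavior = rep_len(behavior, n), hz = hz)
}
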