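#' Window statistics
#'
#' The nine per-channel statistics computed on every observation window:
#' arithmetic mean (`avg`), sample standard deviation with the n-1
#' denominator (`sd`), number of zero crossings after mean-centering
#' (`zc`), peak-to-peak range (`p2p`), root mean square (`rms`), excess
#' kurtosis and skewness from the moment estimators with the n denominator
#' (`kur`, `skw`), crest factor `max(|w|)/rms` (`cf`), and the RMS of the
#' running sum of the signal, the discrete inverse of first differences
#' with zero initial condition (`Vrms`, units g-sample).
#'
#' Zero crossings are counted on the mean-centered signal; without removing
#' the ~1 g gravity offset most channels would never change sign. Samples
#' that land exactly on zero after centering adopt the sign of the previous
#' non-zero sample, so they never contribute a crossing on their own.
#' Degenerate windows (zero variance) return 0 for `skw`, `kur` and `cf`
#' rather than NaN, keeping the feature table rectangular; extraction
#' counts them.
#'
#' @param w Numeric vector of window samples (finite).
#' @return A scalar (named vector of all nine for [window_stats()]).
#' @name window-statistics
NULL

#' @rdname window-statistics
#' @export
zero_crossings <- function(w) {
  s <- sign(w - mean(w))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] * s[-length(s)] < 0)
}

#' @rdname window-statistics
#' @export
crest_factor <- function(w) {
  r <- sqrt(mean(w^2))
  if (r < .Machine$double.eps) return(0)
  max(abs(w)) / r
}

#' @rdname window-statistics
#' @export
vrms <- function(w) {
  sqrt(mean(cumsum(w)^2))
}

skewness_m <- function(w) {
  v <- w - mean(w)
  m2 <- mean(v^2)
  if (m2 < .Machine$double.eps^2) return(0)
  mean(v^3) / m2^1.5
}

kurtosis_m <- function(w) {
  v <- w - mean(w)
  m2 <- mean(v^2)
  if (m2 < .Machine$double.eps^2) return(0)
  mean(v^4) / m2^2 - 3
}

#' @rdname window-statistics
#' @export
window_stats <- function(w) {
  c(avg = mean(w),
    sd = stats::sd(w),
    zc = as.numeric(zero_crossings(w)),
    p2p = max(w) - min(w),
    rms = sqrt(mean(w^2)),
    kur = kurtosis_m(w),
    skw = skewness_m(w),
    cf = crest_factor(w),
    Vrms = vrms(w))
}

#' Feature column names
#'
#' The 36 feature names, channel-major: `x.avg`, `x.sd`, ... `amag.Vrms`.
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  stats_names <- c("avg", "sd", "zc", "p2p", "rms", "kur", "skw", "cf",
                   "Vrms")
  as.vector(vapply(c("x", "y", "z", "amag"),
                   function(ch) paste(ch, stats_names, sep = "."),
                   character(9)))
}

#' Extract the window feature table
#'
#' Computes the nine [window_stats()] on each of the four channels (x, y,
#' z, amag) of every retained window, yielding one tidy row per window with
#' the 36 named features plus the window's labels and provenance.
#'
#' @param ws A [segment_windows()] result.
#' @return A tibble with columns `window_id`, `start_index`, `posture`,
#'   `behavior` (label columns present when the source trace carries them),
#'   and the 36 features of [feature_names()]. The number of degenerate
#'   (zero-variance) channel windows encountered is attached as attribute
#'   `n_degenerate`.
#' @export
extract_features <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  trace <- ws$trace
  if (is.null(trace[["amag"]])) trace <- add_magnitude(trace)
  k <- length(ws$starts)
  fnames <- feature_names()
  if (k == 0) {
    out <- tibble::as_tibble(
      c(list(window_id = integer(0), start_index = integer(0),
             posture = character(0), behavior = character(0)),
        stats::setNames(rep(list(numeric(0)), 36), fnames)))
    attr(out, "n_degenerate") <- 0L
    return(out)
  }
  idx <- outer(seq_len(ws$window) - 1L, ws$starts, `+`)
  feat <- matrix(NA_real_, k, 36, dimnames = list(NULL, fnames))
  n_degen <- 0L
  for (ch in c("x", "y", "z", "amag")) {
    m <- matrix(trace[[ch]][idx], nrow = ws$window)
    vals <- apply(m, 2, window_stats)
    n_degen <- n_degen + sum(vals["sd", ] == 0)
    feat[, paste(ch, rownames(vals), sep = ".")] <- t(vals)
  }
  lab_cols <- list()
  for (mode in c("posture", "behavior")) {
    if (!is.null(trace[[mode]])) {
      lab_cols[[mode]] <- trace[[mode]][ws$starts]
    }
  }
  out <- tibble::as_tibble(c(
    list(window_id = seq_len(k), start_index = ws$starts),
    lab_cols,
    lapply(stats::setNames(fnames, fnames),
           function(fn) unname(feat[, fn]))))
  if (n_degen > 0) {
    message(n_degen, " degenerate (zero-variance) channel window(s); ",
            "skw/kur/cf set to 0 for those")
  }
  attr(out, "n_degenerate") <- n_degen
  out
}

#' Write / read a feature table as CSV
#'
#' @param features A feature table from [extract_features()].
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
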