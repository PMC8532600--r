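fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "cowaccel")
  if (path == "") stop("fixture not found: ", file, call. = FALSE)
  path
}

#' Published confusion matrices
#'
#' The test-set confusion matrices (rows predicted, columns actual) of the
#' four classifiers from the motivating flank-accelerometer study, shipped
#' as fixtures: one set for the posture task (classes RSR, LSR, S; 8,123
#' test rows) and one for the behavior task (five behaviors; 7,565 test
#' rows).
#'
#' @param task `"posture"` or `"behavior"`.
#' @return A named list of four `confusion_matrix` objects (`RF`, `KNN`,
#'   `XGB`, `SVM`).
#' @export
published_confusions <- function(task = c("posture", "behavior")) {
  task <- match.arg(task)
  raw <- utils::read.csv(fixture_path(paste0("confusion_", task, ".csv")),
                         check.names = FALSE)
  classes <- setdiff(names(raw), c("model", "predicted"))
  out <- list()
  for (m in unique(raw$model)) {
    sub <- raw[raw$model == m, ]
    cm <- as.matrix(sub[match(classes, sub$predicted), classes])
    dimnames(cm) <- list(predicted = classes, actual = classes)
    out[[m]] <- as_confusion(cm)
  }
  out
}

#' Published metric tables
#'
#' The printed overall and per-class assessment panels for the same eight
#' model-task combinations, kept as character columns so the printed
#' precision (2 or 3 decimals; p-values as `<0.001`) is preserved for
#' comparison.
#'
#' @inheritParams published_confusions
#' @return A list with tibbles `overall` and `by_class`.
#' @export
published_metrics <- function(task = c("posture", "behavior")) {
  task <- match.arg(task)
  read_chr <- function(f) {
    tibble::as_tibble(utils::read.csv(fixture_path(f),
                                      colClasses = "character",
                                      check.names = FALSE))
  }
  list(overall = read_chr(paste0("reference_overall_", task, ".csv")),
       by_class = read_chr(paste0("reference_byclass_", task, ".csv")))
}

#' Per-animal removal bookkeeping
#'
#' Sample counts before/after removal of non-univocal observations for the
#' twelve observed cows (plus the total row), with the printed
#' minutes-equivalent columns.
#'
#' @return A tibble.
#' @export
cow_observation_table <- function() {
  tibble::as_tibble(utils::read.csv(fixture_path("cow_observations.csv"),
                                    colClasses = c(cow = "character")))
}

# does `computed` agree with the printed string at its own precision?
# "<x" entries match when computed < x. A handful of published entries are
# the truncation rather than the rounding of the underlying ratio, so a
# printed value is accepted when it equals either round(computed, dp) or
# the dp-digit truncation of computed.
matches_printed <- function(printed, computed) {
  mapply(function(p, v) {
    p <- trimws(p)
    if (!is.finite(v)) return(FALSE)
    if (startsWith(p, "<")) return(v < as.numeric(substring(p, 2)))
    dp <- if (grepl("\\.", p)) nchar(sub(".*\\.", "", p)) else 0L
    pnum <- as.numeric(p)
    unit <- 10^(-dp)
    rounded <- abs(v - pnum) <= 0.5 * unit + 1e-9
    truncated <- v - pnum >= -1e-9 && v - pnum < unit - 1e-9
    rounded || truncated
  }, printed, computed, USE.NAMES = FALSE)
}

#' Recompute the published metric tables from the published confusions
#'
#' Runs [metrics_report()] on each of the eight shipped confusion matrices
#' and compares every overall and per-class value with the printed panels,
#' at the precision each value was printed with (half a unit in the last
#' printed decimal; `<0.001` p-values match when the computed p-value is
#' below 0.001).
#'
#' @return A tibble with one row per compared value: `task`, `model`,
#'   `class` (`NA` for overall metrics), `metric`, `printed`, `computed`,
#'   `matches`. The number of mismatches is attached as attribute
#'   `n_mismatch`.
#' @export
reproduce_tables <- function() {
  rows <- list()
  for (task in c("posture", "behavior")) {
    cms <- published_confusions(task)
    ref <- published_metrics(task)
    for (m in names(cms)) {
      rep <- metrics_report(cms[[m]])
      ov_ref <- ref$overall[ref$overall$model == m, ]
      for (metric in setdiff(names(ov_ref), "model")) {
        computed <- switch(metric,
                           accuracy_p_value = rep$overall$accuracy_p_value,
                           rep$overall[[metric]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          task = task, model = m, class = NA_character_, metric = metric,
          printed = ov_ref[[metric]], computed = computed)
      }
      cl_ref <- ref$by_class[ref$by_class$model == m, ]
      for (r in seq_len(nrow(cl_ref))) {
        cls <- cl_ref$class[r]
        comp <- rep$by_class[rep$by_class$class == cls, ]
        for (metric in setdiff(names(cl_ref), c("model", "class"))) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            task = task, model = m, class = cls, metric = metric,
            printed = cl_ref[[metric]][r], computed = comp[[metric]])
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$matches <- matches_printed(out$printed, out$computed)
  attr(out, "n_mismatch") <- sum(!out$matches)
  out
}
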