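#' Read a pipeline run configuration
#'
#' YAML keys mirror the [run_pipeline()] arguments: `mode`, `window`,
#' `stride`, `cutoff`, `train_fraction`, `algorithms`, `seed`,
#' `total_minutes`, `ambiguous_fraction`, `out_dir`, and optionally
#' `sensor_csv` + `annotations_csv` to run on recorded rather than
#' simulated data. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A named list of validated arguments.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("mode", "window", "stride", "cutoff", "train_fraction",
             "algorithms", "seed", "total_minutes", "ambiguous_fraction",
             "out_dir", "sensor_csv", "annotations_csv")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Run the full classification pipeline
#'
#' Orchestrates every stage on one session: obtain a labeled trace (either
#' simulate one from `schedule`, or read `sensor_csv` and label it with
#' `annotations_csv`), remove non-univocal samples for the requested mode,
#' add the magnitude channel, segment into fixed windows, extract the 36
#' features, prune correlated features, split and normalize, then fit each
#' requested classifier and assemble its confusion matrix and metrics
#' report. All randomness derives from `seed` through fixed per-stage
#' offsets, so a rerun with the same inputs is identical.
#'
#' @param schedule A [session_schedule()]; ignored when `sensor_csv` is
#'   given. Defaults to [default_schedule()] with `total_minutes` minutes.
#' @param mode `"posture"` or `"behavior"`.
#' @param algorithms Subset of `c("RF", "KNN", "XGB", "SVM")`.
#' @param window,stride Segmentation parameters (samples).
#' @param cutoff Correlation-pruning threshold.
#' @param train_fraction Training share of the random split.
#' @param seed Integer master seed.
#' @param total_minutes Length of the default simulated session.
#' @param ambiguous_fraction AMBIGUOUS share for the default schedule.
#' @param sensor_csv,annotations_csv Optional recorded-data inputs.
#' @param out_dir Optional directory; when given, the feature table,
#'   retained-feature list, per-model predictions, confusion matrices and
#'   metrics are written there as CSV.
#'
#' @return A list of class `pipeline_run`: `mode`, `removal_report`,
#'   `window_report`, `features`, `prune`, `split`, and per-algorithm
#'   `predictions`, `confusions`, `reports`.
#' @export
run_pipeline <- function(schedule = NULL,
                         mode = c("posture", "behavior"),
                         algorithms = c("RF", "KNN", "XGB", "SVM"),
                         window = 40, stride = 13, cutoff = 0.8,
                         train_fraction = 0.75, seed = 1,
                         total_minutes = 90, ambiguous_fraction = 0.07,
                         sensor_csv = NULL, annotations_csv = NULL,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  algorithms <- match.arg(algorithms, several.ok = TRUE)

  if (!is.null(sensor_csv)) {
    trace <- read_sensor_csv(sensor_csv)
    if (is.null(annotations_csv)) {
      stop("annotations_csv is required with sensor_csv", call. = FALSE)
    }
    trace <- apply_annotations(trace, read_annotations(annotations_csv))
  } else {
    if (is.null(schedule)) {
      schedule <- default_schedule(total_minutes = total_minutes,
                                   ambiguous_fraction = ambiguous_fraction,
                                   seed = seed)
    }
    trace <- simulate_session(schedule)$trace
  }

  dropped <- drop_ambiguous(trace, mode)
  trace <- add_magnitude(dropped$trace)
  ws <- segment_windows(trace, mode = mode, window = window,
                        stride = stride)
  features <- extract_features(ws)
  if (nrow(features) == 0) stop("no windows retained", call. = FALSE)
  prune <- prune_correlated(features, cutoff = cutoff)
  split <- split_normalize(features, train_fraction = train_fraction,
                           seed = seed + 1L, features = prune$retained)

  predictions <- list(); confusions <- list(); reports <- list()
  for (i in seq_along(algorithms)) {
    alg <- algorithms[i]
    pred <- fit_predict(split$train, split$test, algorithm = alg,
                        label = mode, seed = seed + 1L + i,
                        features = prune$retained)
    cm <- build_confusion(actual = split$test[[mode]], predicted = pred,
                          classes = sort(unique(c(split$train[[mode]],
                                                  split$test[[mode]]))))
    predictions[[alg]] <- pred
    confusions[[alg]] <- cm
    reports[[alg]] <- metrics_report(cm)
  }

  run <- structure(list(mode = mode,
                        removal_report = dropped$report,
                        window_report = ws$report,
                        features = features, prune = prune, split = split,
                        predictions = predictions, confusions = confusions,
                        reports = reports),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_csv(run$features, file.path(out_dir, "features.csv"))
  writeLines(run$prune$retained, file.path(out_dir, "retained_features.txt"))
  for (alg in names(run$predictions)) {
    utils::write.csv(
      data.frame(row = seq_along(run$predictions[[alg]]),
                 actual = run$split$test[[run$mode]],
                 predicted = run$predictions[[alg]]),
      file.path(out_dir, paste0("predictions_", alg, ".csv")),
      row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(unclass(run$confusions[[alg]])),
                     file.path(out_dir, paste0("confusion_", alg, ".csv")))
    utils::write.csv(
      cbind(model = alg, as.data.frame(run$reports[[alg]]$overall)),
      file.path(out_dir, paste0("overall_", alg, ".csv")),
      row.names = FALSE, quote = FALSE)
    utils::write.csv(
      cbind(model = alg, as.data.frame(run$reports[[alg]]$by_class)),
      file.path(out_dir, paste0("byclass_", alg, ".csv")),
      row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %s mode, %d windows, %d features retained>\n",
              x$mode, nrow(x$features), length(x$prune$retained)))
  for (alg in names(x$reports)) {
    cat(sprintf("  %-4s accuracy %.3f kappa %.3f\n", alg,
                x$reports[[alg]]$overall$accuracy,
                x$reports[[alg]]$overall$kappa))
  }
  invisible(x)
}
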