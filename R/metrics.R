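#' Build a confusion matrix
#'
#' Counts are laid out predicted-in-rows, actual-in-columns:
#' `counts[i, j]` is the number of test rows predicted as class `i` whose
#' true class is `j`.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param classes Ordered class vector; defaults to the sorted union of the
#'   observed labels.
#' @return An integer matrix of class `confusion_matrix` with dimnames
#'   `predicted` and `actual`.
#' @export
build_confusion <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) == 0) stop("empty label vectors", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad) > 0) {
    stop("labels outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(predicted, classes), factor(actual, classes))
  as_confusion(unclass(matrix(as.integer(counts), nrow = length(classes),
                              dimnames = list(predicted = classes,
                                              actual = classes))))
}

#' @rdname build_confusion
#' @param m A square count matrix (rows predicted, columns actual) to wrap
#'   directly, e.g. a published table.
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0), sum(m) > 0)
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(paste0("class", seq_len(nrow(m))),
                        paste0("class", seq_len(nrow(m))))
  }
  names(dimnames(m)) <- c("predicted", "actual")
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = predicted, columns = actual)\n")
  print(unclass(x))
  invisible(x)
}

# one-vs-rest counts per class; TP on the diagonal
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  tn <- total - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn, total = total)
}

#' Overall model assessment
#'
#' Accuracy (diagonal over total), Cohen's kappa (accuracy corrected for
#' the chance agreement implied by the marginals), the exact 95%
#' Clopper-Pearson binomial confidence interval for accuracy, the
#' no-information rate (largest actual-class share), and the one-sided
#' exact binomial p-value for accuracy exceeding the no-information rate.
#'
#' @param cm A [build_confusion()] matrix.
#' @param conf_level Confidence level for the accuracy interval.
#' @return A one-row tibble: `accuracy`, `kappa`, `accuracy_lower`,
#'   `accuracy_upper`, `nir`, `accuracy_p_value`. `kappa` is `NA` when the
#'   chance agreement is 1 (a single class on both axes).
#' @export
overall_metrics <- function(cm, conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  correct <- sum(diag(cm))
  accuracy <- correct / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) {
    NA_real_
  } else {
    (accuracy - pe) / (1 - pe)
  }
  ci <- stats::binom.test(correct, total,
                          conf.level = conf_level)$conf.int
  nir <- max(colSums(cm)) / total
  p_val <- stats::binom.test(correct, total, p = nir,
                             alternative = "greater")$p.value
  tibble::tibble(accuracy = accuracy, kappa = kappa,
                 accuracy_lower = ci[1], accuracy_upper = ci[2],
                 nir = nir, accuracy_p_value = p_val)
}

#' Per-class assessment panel
#'
#' One-vs-rest sensitivity, specificity, precision (positive predictive
#' value), negative predictive value, prevalence (actual-class share), and
#' balanced accuracy (mean of sensitivity and specificity) for every
#' class. Undefined ratios (zero denominators) are returned as `NA`.
#'
#' @param cm A [build_confusion()] matrix.
#' @return A tibble with one row per class.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  oc <- ovr_counts(cm)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- unname(safe_div(oc$tp, oc$tp + oc$fn))
  spec <- unname(safe_div(oc$tn, oc$tn + oc$fp))
  tibble::tibble(
    class = rownames(cm),
    sensitivity = sens,
    specificity = spec,
    precision = unname(safe_div(oc$tp, oc$tp + oc$fp)),
    npv = unname(safe_div(oc$tn, oc$tn + oc$fn)),
    prevalence = unname((oc$tp + oc$fn) / oc$total),
    balanced_accuracy = (sens + spec) / 2)
}

#' Full metrics report
#'
#' @param cm A [build_confusion()] matrix.
#' @param conf_level Confidence level for the accuracy interval.
#' @return A list of class `metrics_report` with elements `overall`
#'   ([overall_metrics()]) and `by_class` ([class_metrics()]).
#' @export
metrics_report <- function(cm, conf_level = 0.95) {
  structure(list(overall = overall_metrics(cm, conf_level),
                 by_class = class_metrics(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  ov <- x$overall
  cat(sprintf(
    "Accuracy %.3f (95%% CI %.3f-%.3f), kappa %.3f, NIR %.3f, p %s\n",
    ov$accuracy, ov$accuracy_lower, ov$accuracy_upper, ov$kappa,
    ov$nir,
    if (ov$accuracy_p_value < 0.001) "<0.001"
    else sprintf("%.3f", ov$accuracy_p_value)))
  print(as.data.frame(x$by_class), digits = 3)
  invisible(x)
}
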