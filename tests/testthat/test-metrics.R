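test_that("confusion counts are predicted-by-actual tallies", {
  actual <- c("a", "a", "b", "b", "b", "c")
  predicted <- c("a", "b", "b", "b", "a", "c")
  cm <- build_confusion(actual, predicted, classes = c("a", "b", "c"))
  # hand tally: pred a/actual a = 1, pred b/actual a = 1, pred a/actual b = 1,
  # pred b/actual b = 2, pred c/actual c = 1
  expect_equal(unclass(cm),
               matrix(c(1, 1, 0, 1, 2, 0, 0, 0, 1), 3,
                      dimnames = list(predicted = c("a", "b", "c"),
                                      actual = c("a", "b", "c"))),
               ignore_attr = "class")

  all_right <- build_confusion(actual, actual)
  expect_true(all(all_right[upper.tri(all_right)] == 0))
  expect_true(all(all_right[lower.tri(all_right)] == 0))

  expect_error(build_confusion(actual, predicted[-1]), "equal length")
  expect_error(build_confusion(character(0), character(0)), "empty")
})

test_that("overall metrics behave at the closed-form corners", {
  perfect <- build_confusion(c("a", "b", "b"), c("a", "b", "b"))
  ov <- overall_metrics(perfect)
  expect_equal(ov$accuracy, 1)
  expect_equal(ov$kappa, 1)
  expect_true(ov$accuracy_upper == 1)

  chance <- as_confusion(matrix(c(25, 25, 25, 25), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  ovc <- overall_metrics(chance)
  expect_equal(ovc$accuracy, 0.5)
  expect_equal(ovc$kappa, 0)
  expect_equal(ovc$nir, 0.5)

  # a single class on both axes: chance agreement is 1, kappa undefined
  degenerate <- as_confusion(matrix(10, 1, 1,
                                    dimnames = list("a", "a")))
  expect_true(is.na(overall_metrics(degenerate)$kappa))
})

test_that("published RF posture matrix yields the printed overall and class values", {
  cm <- published_confusions("posture")$RF
  ov <- overall_metrics(cm)
  expect_equal(round(ov$accuracy, 3), 0.988)
  expect_equal(round(ov$kappa, 3), 0.978)
  expect_lt(ov$accuracy_p_value, 0.001)
  expect_equal(ov$nir, 4862 / 8123)

  cl <- class_metrics(cm)
  rsr <- cl[cl$class == "RSR", ]
  expect_equal(rsr$sensitivity, 2058 / 2059)
  expect_equal(rsr$precision, 2058 / 2067)
  expect_equal(round(rsr$precision, 3), 0.996)
  expect_equal(round(rsr$balanced_accuracy, 3), 0.999)
})

test_that("per-class panel handles degenerate and symmetric matrices", {
  # class b never occurs in actual: sensitivity undefined, specificity not
  m <- as_confusion(matrix(c(2, 1, 0, 0), 2,
                           dimnames = list(c("a", "b"), c("a", "b"))))
  cl <- class_metrics(m)
  expect_true(is.na(cl$sensitivity[cl$class == "b"]))
  expect_false(is.na(cl$specificity[cl$class == "b"]))

  sym <- as_confusion(matrix(c(8, 2, 2, 8), 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  cls <- class_metrics(sym)
  for (col in c("sensitivity", "specificity", "precision", "npv",
                "balanced_accuracy")) {
    expect_equal(cls[[col]][1], cls[[col]][2])
  }
})

test_that("panel invariants hold and permutation only reorders rows", {
  set.seed(61)
  actual <- sample(posture_levels(), 500, replace = TRUE)
  predicted <- ifelse(runif(500) < 0.7, actual,
                      sample(posture_levels(), 500, replace = TRUE))
  cm <- build_confusion(actual, predicted, classes = posture_levels())
  cl <- class_metrics(cm)
  ov <- overall_metrics(cm)

  expect_equal(sum(cl$prevalence), 1)
  expect_equal(ov$accuracy, mean(predicted == actual))  # direct oracle
  oc <- sum(diag(cm))
  expect_equal(oc / sum(cm), ov$accuracy)
  expect_equal(cl$balanced_accuracy,
               (cl$sensitivity + cl$specificity) / 2)

  perm <- c("LSR", "S", "RSR")
  cm2 <- build_confusion(actual, predicted, classes = perm)
  cl2 <- class_metrics(cm2)
  expect_equal(cl2[match(cl$class, cl2$class), ], cl,
               ignore_attr = TRUE)
  expect_equal(overall_metrics(cm2)$kappa, ov$kappa)
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(71)
  actual <- factor(sample(behavior_levels(), 400, replace = TRUE))
  predicted <- factor(
    ifelse(runif(400) < 0.6, as.character(actual),
           sample(behavior_levels(), 400, replace = TRUE)),
    levels = levels(actual))
  cm <- build_confusion(as.character(actual), as.character(predicted),
                        classes = levels(actual))
  ref <- caret::confusionMatrix(predicted, actual)
  ov <- overall_metrics(cm)
  expect_equal(unname(ov$accuracy), unname(ref$overall["Accuracy"]))
  expect_equal(unname(ov$kappa), unname(ref$overall["Kappa"]))
  expect_equal(unname(ov$accuracy_lower), unname(ref$overall["AccuracyLower"]))
  expect_equal(unname(ov$accuracy_upper), unname(ref$overall["AccuracyUpper"]))
  expect_equal(unname(ov$accuracy_p_value),
               unname(ref$overall["AccuracyPValue"]))
  cl <- class_metrics(cm)
  expect_equal(cl$sensitivity, unname(ref$byClass[, "Sensitivity"]))
  expect_equal(cl$specificity, unname(ref$byClass[, "Specificity"]))
  expect_equal(cl$precision, unname(ref$byClass[, "Pos Pred Value"]))
  expect_equal(cl$npv, unname(ref$byClass[, "Neg Pred Value"]))
  expect_equal(cl$prevalence, unname(ref$byClass[, "Prevalence"]))
  expect_equal(cl$balanced_accuracy,
               unname(ref$byClass[, "Balanced Accuracy"]))
})

test_that("kappa is 1 exactly when the off-diagonal is empty", {
  diag_cm <- as_confusion(diag(c(5, 7, 9)))
  expect_equal(overall_metrics(diag_cm)$kappa, 1)
  off <- as_confusion(diag(c(5, 7, 9)) + matrix(c(0, 1, rep(0, 7)), 3))
  expect_lt(overall_metrics(off)$kappa, 1)
})
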