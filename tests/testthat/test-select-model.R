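make_feature_toy <- function(n = 200, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  tibble::tibble(
    f1 = a,
    f2 = a + rnorm(n, sd = 0.05),   # near-duplicate of f1
    f3 = rnorm(n),
    f4 = rnorm(n))
}

test_that("one member of a duplicated pair is removed, nothing else", {
  toy <- make_feature_toy()
  pr <- prune_correlated(toy, cutoff = 0.8,
                         features = c("f1", "f2", "f3", "f4"))
  expect_length(pr$removed, 1)
  expect_true(pr$removed %in% c("f1", "f2"))
  expect_setequal(c(pr$removed, pr$retained), c("f1", "f2", "f3", "f4"))

  pr_loose <- prune_correlated(toy, cutoff = 1.0,
                               features = c("f1", "f2", "f3", "f4"))
  expect_length(pr_loose$removed, 0)

  expect_error(prune_correlated(toy, features = "f1"), "at least 2")
})

test_that("greedy removal matches the exhaustive minimal-subset oracle on a small table", {
  set.seed(12)
  n <- 300
  base1 <- rnorm(n); base2 <- rnorm(n)
  toy <- tibble::tibble(
    g1 = base1,
    g2 = base1 + rnorm(n, sd = 0.1),
    g3 = base1 + rnorm(n, sd = 0.12),
    g4 = base2,
    g5 = rnorm(n))
  cutoff <- 0.8
  pr <- prune_correlated(toy, cutoff = cutoff,
                         features = paste0("g", 1:5))
  minimal <- oracle_min_removals(as.matrix(toy), cutoff)
  min_size <- length(minimal[[1]])
  expect_length(pr$removed, min_size)
  expect_true(any(vapply(minimal, setequal, logical(1), y = pr$removed)))
})

test_that("after pruning no retained pair reaches the cutoff", {
  sess <- simulate_session(default_schedule(total_minutes = 20, seed = 41))
  tr <- add_magnitude(drop_ambiguous(sess$trace, "behavior")$trace)
  ft <- extract_features(segment_windows(tr, "behavior"))
  pr <- prune_correlated(ft, cutoff = 0.8)
  C <- abs(stats::cor(as.matrix(ft[, pr$retained])))
  diag(C) <- 0
  expect_lt(max(C), 0.8)
  expect_length(intersect(pr$removed, pr$retained), 0)
})

test_that("the split partitions rows and normalizes with training statistics", {
  toy <- make_feature_toy(n = 100, seed = 3)
  toy$posture <- rep(c("S", "RSR"), 50)
  sp <- split_normalize(toy, train_fraction = 0.75, seed = 5,
                        features = paste0("f", 1:4))
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  for (f in paste0("f", 1:4)) {
    expect_equal(mean(sp$train[[f]]), 0, tolerance = 1e-10)
    expect_equal(sd(sp$train[[f]]), 1, tolerance = 1e-10)
  }
  # test rows are transformed with the training center/scale
  raw_test <- toy[-sp$idx_train, ]
  expect_equal(sp$test$f1, (raw_test$f1 - sp$center["f1"]) / sp$scale["f1"],
               ignore_attr = TRUE)
  expect_length(intersect(sp$idx_train, setdiff(seq_len(100), sp$idx_train)),
                0)
  # same seed, same split
  sp2 <- split_normalize(toy, train_fraction = 0.75, seed = 5,
                         features = paste0("f", 1:4))
  expect_identical(sp$train, sp2$train)

  toy$flat <- 1
  expect_error(split_normalize(toy, seed = 5,
                               features = c("f1", "flat")), "flat")
})

test_that("all four backends solve a widely separated two-class problem", {
  set.seed(8)
  n <- 200
  lab <- rep(c("a", "b"), each = n / 2)
  shift <- ifelse(lab == "a", -5, 5)   # 10 sd separation
  toy <- tibble::tibble(f1 = rnorm(n) + shift, f2 = rnorm(n) - shift,
                        posture = lab)
  sp <- split_normalize(toy, seed = 9, features = c("f1", "f2"))
  for (alg in c("RF", "KNN", "XGB", "SVM")) {
    pred <- fit_predict(sp$train, sp$test, algorithm = alg,
                        label = "posture", seed = 10,
                        features = c("f1", "f2"))
    expect_equal(mean(pred == sp$test$posture), 1.0)
  }
})

test_that("1-nearest-neighbor on identical train and test is exact", {
  toy <- make_feature_toy(n = 60, seed = 13)
  toy$posture <- sample(c("S", "RSR", "LSR"), 60, replace = TRUE)
  pred <- fit_predict(toy, toy, algorithm = "KNN", label = "posture",
                      hyper = list(k = 1), features = paste0("f", 1:4))
  expect_equal(pred, toy$posture)
})

test_that("seeded RF and XGB predictions are reproducible", {
  sess <- simulate_session(default_schedule(total_minutes = 15, seed = 17))
  tr <- add_magnitude(drop_ambiguous(sess$trace, "posture")$trace)
  ft <- extract_features(segment_windows(tr, "posture"))
  sp <- split_normalize(ft, seed = 19)
  for (alg in c("RF", "XGB")) {
    p1 <- fit_predict(sp$train, sp$test, algorithm = alg,
                      label = "posture", seed = 23)
    p2 <- fit_predict(sp$train, sp$test, algorithm = alg,
                      label = "posture", seed = 23)
    expect_identical(p1, p2)
  }
})

test_that("every backend recovers posture on default synthetic sessions", {
  run <- run_pipeline(mode = "posture",
                      algorithms = c("RF", "KNN", "XGB", "SVM"),
                      seed = 29, total_minutes = 60)
  for (alg in names(run$reports)) {
    expect_gte(run$reports[[alg]]$overall$accuracy, 0.95)
  }
})
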