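feature_columns <- function(table) {
  intersect(feature_names(), names(table))
}

#' Remove highly correlated features
#'
#' Greedy pairwise filter: while any pair of retained features has absolute
#' Pearson correlation at or above `cutoff`, take the worst (largest |r|)
#' pair and drop the member with the larger mean absolute correlation
#' against all remaining features. Constant columns are dropped up front
#' (correlation with them is undefined). The procedure is deterministic
#' given the table.
#'
#' @param table A feature table ([extract_features()] output or any data
#'   frame containing feature columns).
#' @param cutoff Absolute-correlation threshold (default 0.8); pairs with
#'   `|r| >= cutoff` are broken up.
#' @param features Which columns to consider (default: the [feature_names()]
#'   present in the table, else all numeric non-id columns).
#'
#' @return A list of class `prune_result`: `removed` (in removal order),
#'   `retained`, `correlation_matrix` (absolute correlations of the
#'   non-constant features), `constant` (columns dropped as constant), and
#'   `cutoff`.
#' @export
prune_correlated <- function(table, cutoff = 0.8, features = NULL) {
  if (is.null(features)) {
    features <- feature_columns(table)
    if (length(features) == 0) {
      features <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          c("window_id", "start_index"))
    }
  }
  if (length(features) < 2) {
    stop("need at least 2 features to prune", call. = FALSE)
  }
  if (nrow(table) < 2) stop("need at least 2 rows", call. = FALSE)
  X <- as.matrix(table[, features, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  constant <- features[sds == 0]
  if (length(constant) > 0) {
    message("dropping constant feature(s) before pruning: ",
            paste(constant, collapse = ", "))
  }
  active <- setdiff(features, constant)
  C <- abs(stats::cor(X[, active, drop = FALSE]))
  C_full <- C
  removed <- character(0)
  repeat {
    if (ncol(C) < 2) break
    D <- C
    diag(D) <- 0
    mx <- max(D)
    if (mx < cutoff) break
    pair <- which(D == mx, arr.ind = TRUE)[1, ]
    i <- pair[["row"]]; j <- pair[["col"]]
    mean_i <- mean(D[i, -i]); mean_j <- mean(D[j, -j])
    drop_idx <- if (mean_i >= mean_j) i else j
    removed <- c(removed, colnames(C)[drop_idx])
    C <- C[-drop_idx, -drop_idx, drop = FALSE]
  }
  structure(list(removed = removed,
                 retained = setdiff(active, removed),
                 correlation_matrix = C_full,
                 constant = constant,
                 cutoff = cutoff),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("<prune_result: removed %d of %d features at |r| >= %g>\n",
              length(x$removed), length(x$removed) + length(x$retained),
              x$cutoff))
  if (length(x$removed) > 0) {
    cat("removed:", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Random train/test split with training-statistics normalization
#'
#' Splits the rows uniformly at random (not stratified, not grouped by
#' animal) into training and testing partitions, then z-scores every
#' feature column in both partitions using the mean and standard deviation
#' of the *training* rows only.
#'
#' @param table A feature table.
#' @param train_fraction Proportion of rows assigned to training
#'   (default 0.75).
#' @param seed Optional integer seed; the split is deterministic given it.
#' @param features Feature columns to normalize (default as in
#'   [prune_correlated()]).
#'
#' @return A list of class `split_result`: `train`, `test` (tibbles),
#'   `center`, `scale` (named training statistics), `features`, and
#'   `idx_train` (row indices of the training partition).
#' @export
split_normalize <- function(table, train_fraction = 0.75, seed = NULL,
                            features = NULL) {
  stopifnot(nrow(table) > 1, train_fraction > 0, train_fraction < 1)
  if (is.null(features)) {
    features <- feature_columns(table)
    if (length(features) == 0) {
      features <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          c("window_id", "start_index"))
    }
  }
  n <- nrow(table)
  if (!is.null(seed)) set.seed(seed)
  idx_train <- sort(sample.int(n, round(n * train_fraction)))
  train <- table[idx_train, ]
  test <- table[-idx_train, ]
  center <- vapply(train[, features, drop = FALSE], mean, numeric(1))
  scale <- vapply(train[, features, drop = FALSE], stats::sd, numeric(1))
  zero_sd <- features[scale == 0]
  if (length(zero_sd) > 0) {
    stop("training standard deviation is zero for feature(s): ",
         paste(zero_sd, collapse = ", "), call. = FALSE)
  }
  for (f in features) {
    train[[f]] <- (train[[f]] - center[f]) / scale[f]
    test[[f]] <- (test[[f]] - center[f]) / scale[f]
  }
  structure(list(train = train, test = test, center = center, scale = scale,
                 features = features, idx_train = idx_train),
            class = "split_result")
}

default_hyperparameters <- function(algorithm, p) {
  switch(algorithm,
         RF = list(ntree = 500, mtry = max(1, floor(sqrt(p)))),
         KNN = list(k = 5),
         XGB = list(nrounds = 200, max_depth = 6, eta = 0.3),
         SVM = list(cost = 1, gamma = 1 / p))
}

#' Train a classifier and predict the test rows
#'
#' The four backends of the pipeline: random forest (`RF`), k-nearest
#' neighbors (`KNN`, Euclidean), extreme gradient boosting (`XGB`,
#' multiclass softmax), and a radial-kernel support vector machine
#' (`SVM`). Hyperparameters default to standard values (RF: 500 trees,
#' sqrt(p) candidates per split; KNN: k = 5; XGB: 200 rounds, depth 6, eta
#' 0.3; SVM: C = 1, gamma = 1/p) and can be overridden via `hyper`.
#' Randomized backends are reproducible given `seed`.
#'
#' @param train,test Normalized feature tables (e.g. from
#'   [split_normalize()]); `train` must carry the `label` column.
#' @param algorithm `"RF"`, `"KNN"`, `"XGB"` or `"SVM"`.
#' @param label Name of the label column (`"posture"` or `"behavior"`).
#' @param hyper Named list of hyperparameter overrides.
#' @param seed Optional integer seed.
#' @param features Feature columns used as predictors (default: the
#'   [feature_names()] present in `train`).
#'
#' @return Character vector of predicted labels, one per test row.
#' @export
fit_predict <- function(train, test, algorithm = c("RF", "KNN", "XGB", "SVM"),
                        label = "posture", hyper = list(), seed = NULL,
                        features = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(features)) features <- feature_columns(train)
  stopifnot(length(features) >= 1, !is.null(train[[label]]))
  Xtr <- as.matrix(train[, features, drop = FALSE])
  Xte <- as.matrix(test[, features, drop = FALSE])
  ytr <- factor(train[[label]])
  hp <- utils::modifyList(default_hyperparameters(algorithm, ncol(Xtr)),
                          hyper)
  if (!is.null(seed)) set.seed(seed)
  pred <- switch(
    algorithm,
    RF = {
      fit <- randomForest::randomForest(x = Xtr, y = ytr,
                                        ntree = hp$ntree, mtry = hp$mtry)
      as.character(stats::predict(fit, Xte))
    },
    KNN = as.character(class::knn(Xtr, Xte, ytr, k = hp$k)),
    XGB = {
      dtr <- xgboost::xgb.DMatrix(Xtr,
                                  label = as.integer(ytr) - 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = nlevels(ytr),
                      max_depth = hp$max_depth, eta = hp$eta,
                      nthread = 1),
        data = dtr, nrounds = hp$nrounds, verbose = 0)
      cls <- stats::predict(fit, xgboost::xgb.DMatrix(Xte))
      levels(ytr)[cls + 1L]
    },
    SVM = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = hp$cost,
                        gamma = hp$gamma)
      as.character(stats::predict(fit, Xte))
    })
  pred
}
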