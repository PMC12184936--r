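# Mode-choice classification: correlation pruning, near-miss rebalancing,
# stratified splitting, grid-search tuning and random-forest training.
# The forest itself comes from the randomForest package (bagging + random
# feature selection, Gini impurity, unlimited depth, min split size 2 -- its
# defaults); everything around it is authored here because the selection,
# rebalancing and tie-break rules are part of the method under test.

ID_COLS <- c("individual_id", "origin_cell", "dest_cell")

# Canonical class order: (car, bicycle, walk) whenever the labels are the
# three travel modes, alphabetical otherwise (toy data in tests).
mode_levels <- function(vals) {
  u <- unique(as.character(vals))
  if (all(u %in% MODES)) intersect(MODES, u) else sort(u)
}

feature_columns <- function(table, response = "mode") {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  setdiff(num, c(ID_COLS, response))
}

#' Default keep-list for correlation pruning
#'
#' The POI categories retained after pruning highly correlated POI counts:
#' retail, educational, recreational and medical (health).
#' @return character vector of column names
#' @export
default_keep_list <- function() {
  c("mean_poi_retail", "mean_poi_educational", "mean_poi_recreational", "mean_poi_medical")
}

#' Drop features until no pair is correlated beyond a threshold
#'
#' Iteratively removes, from each offending pair (|Pearson r| > threshold),
#' the feature with the larger mean absolute correlation to all remaining
#' features (ties drop the later column). Columns in \code{keep} are never
#' dropped; constant columns are excluded with a warning (their correlation
#' is undefined).
#'
#' @param table trip table (or any data frame with numeric features)
#' @param threshold maximum tolerated |Pearson r| (default 0.8)
#' @param keep columns forced to be retained
#' @param response response column name, excluded from pruning
#' @return character vector of retained feature names, in original order
#' @export
prune_correlated <- function(table, threshold = 0.8, keep = NULL, response = "mode") {
  feats <- feature_columns(table, response)
  if (length(feats) < 2L) rx_stop("invalid_config", "need at least 2 numeric feature columns")
  sds <- vapply(feats, function(f) stats::sd(table[[f]]), 0)
  if (any(sds == 0 | is.na(sds))) {
    cst <- feats[sds == 0 | is.na(sds)]
    rx_warn(sprintf("excluding constant column(s): %s", paste(cst, collapse = ", ")))
    feats <- setdiff(feats, cst)
  }
  keep <- intersect(keep, feats)
  active <- feats
  repeat {
    X <- as.matrix(table[active])
    R <- abs(stats::cor(X))
    diag(R) <- 0
    viol <- which(R > threshold, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol)) {
      droppable <- !(active %in% keep)
      viol <- viol[droppable[viol[, 1]] | droppable[viol[, 2]], , drop = FALSE]
    }
    if (!nrow(viol)) break
    meanabs <- rowMeans(R) * length(active) / (length(active) - 1)
    # candidate victims: any droppable member of a violating pair
    cand <- unique(c(viol[, 1], viol[, 2]))
    cand <- cand[!(active[cand] %in% keep)]
    # drop the one with the largest mean |r|; ties -> later column
    worst <- cand[order(-meanabs[cand], -cand)][1]
    active <- active[-worst]
    if (length(active) < 2L) break
  }
  feats[feats %in% active]
}

#' Near-miss undersampling to the minority-class size
#'
#' Distances are computed on a z-scored copy of the features (original
#' values are returned). For each majority class, each point's mean distance
#' to its 3 nearest minority-class points is ranked; the
#' \code{"keep-closest"} variant (standard near-miss) retains the points
#' closest to the minority class, \code{"remove-closest"} retains the
#' farthest (the variant matching a literal reading of removing majority
#' points most similar to the minority).
#'
#' @param X numeric feature data frame or matrix
#' @param y class labels (factor or character)
#' @param variant \code{"keep-closest"} (default) or \code{"remove-closest"}
#' @param k number of minority neighbours to average (default 3)
#' @return list with \code{X}, \code{y} (every class at the minority count)
#'   and \code{idx}, the retained row indices of the input (ascending)
#' @export
nearmiss_undersample <- function(X, y, variant = c("keep-closest", "remove-closest"), k = 3) {
  variant <- match.arg(variant)
  y <- as.factor(y)
  counts <- table(y)
  if (length(counts) < 2L) rx_stop("class_missing", "need at least 2 classes")
  if (any(counts == 0))
    rx_stop("class_missing", sprintf("class with 0 rows: %s",
                                     paste(names(counts)[counts == 0], collapse = ", ")))
  Xm <- as.matrix(as.data.frame(X)[vapply(as.data.frame(X), is.numeric, TRUE)])
  mu <- colMeans(Xm); sg <- apply(Xm, 2, stats::sd)
  sg[sg == 0 | is.na(sg)] <- 1
  Z <- sweep(sweep(Xm, 2, mu), 2, sg, "/")
  n_min <- min(counts)
  minority <- names(counts)[which.min(counts)]   # first minimum: stable
  min_rows <- which(y == minority)
  keep_idx <- min_rows
  kk <- min(k, length(min_rows))
  Zmin <- Z[min_rows, , drop = FALSE]
  for (cl in setdiff(levels(y), minority)) {
    rows <- which(y == cl)
    if (length(rows) <= n_min) { keep_idx <- c(keep_idx, rows); next }
    meand <- numeric(length(rows))
    chunk <- 512L
    for (lo in seq(1L, length(rows), by = chunk)) {
      hi <- min(length(rows), lo + chunk - 1L)
      A <- Z[rows[lo:hi], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(Zmin^2), "+") - 2 * A %*% t(Zmin)
      d2[d2 < 0] <- 0
      d <- sqrt(d2)
      meand[lo:hi] <- apply(d, 1, function(v) mean(sort(v)[seq_len(kk)]))
    }
    ord <- if (variant == "keep-closest") order(meand, rows) else order(-meand, rows)
    keep_idx <- c(keep_idx, rows[ord[seq_len(n_min)]])
  }
  keep_idx <- sort(keep_idx)
  list(X = as.data.frame(X)[keep_idx, , drop = FALSE],
       y = droplevels(y[keep_idx]),
       idx = keep_idx)
}

#' Stratified train/test split
#'
#' Partitions the table into disjoint, exhaustive train and test sets,
#' stratified by the response so the test set keeps the original class
#' distribution. Rebalancing, when used, is applied to the training
#' partition only.
#'
#' @param table trip table
#' @param test_fraction fraction of rows held out (default 0.30)
#' @param seed integer seed; the same seed always gives the same partition
#' @param response response column (default \code{"mode"})
#' @return list with \code{train} and \code{test} data frames
#' @export
split_trips <- function(table, test_fraction = 0.30, seed = 1, response = "mode") {
  if (!nrow(table)) rx_stop("invalid_config", "table is empty")
  if (test_fraction <= 0 || test_fraction >= 1)
    rx_stop("invalid_config", "test_fraction must be in (0, 1)")
  y <- as.factor(table[[response]])
  if (any(table(y) == 0))
    rx_stop("stratification", sprintf("mode absent from table: %s",
                                      paste(levels(y)[table(y) == 0], collapse = ", ")))
  test_rows <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      n_test <- round(length(rows) * test_fraction)
      if (n_test == 0 && length(rows) > 1) n_test <- 1
      sample(rows, n_test)
    }), use.names = FALSE)
  })
  if (!length(test_rows)) rx_stop("invalid_config", "test partition would be empty")
  list(train = table[-test_rows, , drop = FALSE],
       test = table[test_rows, , drop = FALSE])
}

#' Model configuration
#'
#' @param correlation_threshold |Pearson r| above which a feature pair is
#'   pruned (default 0.8)
#' @param test_fraction held-out share (default 0.30)
#' @param tree_grid ensemble sizes searched (default \code{c(100, 300,
#'   500)})
#' @param max_features_grid candidate features per split searched; NULL
#'   means 1..p at tuning time
#' @param n_trees_final,max_features_final fixed values; when both are set,
#'   tuning is skipped
#' @param nearmiss_variant \code{"keep-closest"} or \code{"remove-closest"}
#' @param keep_list columns never pruned (default
#'   \code{\link{default_keep_list}})
#' @param seed integer seed governing split, rebalance, tuning and training
#' @return a \code{model_config} list
#' @export
model_config <- function(correlation_threshold = 0.8,
                         test_fraction = 0.30,
                         tree_grid = c(100, 300, 500),
                         max_features_grid = NULL,
                         n_trees_final = NULL,
                         max_features_final = NULL,
                         nearmiss_variant = c("keep-closest", "remove-closest"),
                         keep_list = default_keep_list(),
                         seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    rx_stop("invalid_config", "test_fraction must be in (0, 1)")
  if (!length(tree_grid)) rx_stop("invalid_config", "tree_grid must be non-empty")
  structure(list(correlation_threshold = correlation_threshold,
                 test_fraction = test_fraction,
                 tree_grid = as.integer(tree_grid),
                 max_features_grid = if (is.null(max_features_grid)) NULL else as.integer(max_features_grid),
                 n_trees_final = n_trees_final,
                 max_features_final = max_features_final,
                 nearmiss_variant = match.arg(nearmiss_variant),
                 keep_list = keep_list,
                 seed = check_count(seed, "seed")),
            class = "model_config")
}

#' Grid-search the forest hyperparameters by 3-fold cross-validation
#'
#' Evaluates every (n_trees, max_features) grid point by stratified 3-fold
#' cross-validated accuracy on the (already rebalanced, pruned) training
#' set. The best point wins; exact ties prefer fewer trees, then fewer
#' features. Grid points with more features than available are skipped with
#' a warning.
#'
#' @param train training data frame containing the response and only the
#'   retained features
#' @param config a \code{\link{model_config}}
#' @param response response column
#' @return list with \code{n_trees}, \code{max_features} and the full
#'   accuracy \code{grid} data frame
#' @export
tune_forest <- function(train, config = model_config(), response = "mode") {
  feats <- feature_columns(train, response)
  p <- length(feats)
  fgrid <- config$max_features_grid %||% seq_len(p)
  if (any(fgrid > p)) {
    rx_warn(sprintf("skipping max_features > %d: %s", p,
                    paste(fgrid[fgrid > p], collapse = ", ")))
    fgrid <- fgrid[fgrid <= p]
  }
  if (!length(fgrid)) rx_stop("invalid_config", "no feasible max_features in grid")
  y <- factor(train[[response]], levels = mode_levels(train[[response]]))
  folds <- with_seed(derive_seed(config$seed, 91L), {
    f <- integer(nrow(train))
    for (cl in levels(y)) {
      rows <- which(y == cl)
      f[rows] <- sample(rep_len(1:3, length(rows)))
    }
    f
  })
  grid <- expand.grid(n_trees = config$tree_grid, max_features = fgrid)
  grid$accuracy <- NA_real_
  X <- train[feats]
  for (gi in seq_len(nrow(grid))) {
    acc <- numeric(3)
    for (fold in 1:3) {
      tr <- folds != fold
      fit <- with_seed(derive_seed(config$seed, 92L + fold),
                       randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                                  ntree = grid$n_trees[gi],
                                                  mtry = grid$max_features[gi]))
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      acc[fold] <- mean(pred == y[!tr])
    }
    grid$accuracy[gi] <- mean(acc)
  }
  best <- grid[order(-grid$accuracy, grid$n_trees, grid$max_features), ][1, ]
  list(n_trees = best$n_trees, max_features = best$max_features, grid = grid)
}

#' Train the bagged-tree ensemble
#'
#' Wraps \code{randomForest}: \code{n_trees} trees, each grown on a
#' bootstrap resample with \code{max_features} candidate features per split,
#' remaining hyperparameters at their defaults (unlimited depth, minimum
#' split size 2, Gini impurity). The out-of-bag accuracy is recorded and the
#' returned model predicts per-class vote fractions.
#'
#' @param train training data frame (response + features)
#' @param n_trees ensemble size (>= 1)
#' @param max_features candidate features per split
#' @param seed integer seed (fixing it fixes the model)
#' @param response response column
#' @return a \code{forest_model}
#' @export
train_forest <- function(train, n_trees, max_features, seed = 1, response = "mode") {
  if (!is.numeric(n_trees) || n_trees < 1) rx_stop("invalid_config", "n_trees must be >= 1")
  feats <- feature_columns(train, response)
  if (max_features > length(feats))
    rx_stop("invalid_config", "max_features exceeds the number of features")
  y <- factor(train[[response]], levels = mode_levels(train[[response]]))
  rf <- with_seed(seed,
                  randomForest::randomForest(x = train[feats], y = y,
                                             ntree = as.integer(n_trees),
                                             mtry = as.integer(max_features),
                                             importance = FALSE))
  structure(list(rf = rf, features = feats, classes = levels(y),
                 n_trees = as.integer(n_trees), max_features = as.integer(max_features),
                 seed = seed,
                 oob_accuracy = 1 - unname(rf$err.rate[n_trees, "OOB"])),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, %d features/split, %d features, OOB accuracy %.3f\n",
              x$n_trees, x$max_features, length(x$features), x$oob_accuracy))
  invisible(x)
}

#' Per-class vote fractions for new data
#'
#' @param model a \code{forest_model}
#' @param newdata data frame containing the model's features
#' @return matrix (rows = observations, cols = classes in fixed order),
#'   rows summing to 1
#' @export
predict_votes <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing))
    rx_stop("schema", sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")))
  v <- stats::predict(model$rf, newdata[model$features], type = "prob")
  v[, model$classes, drop = FALSE]
}

#' Evaluate a forest on held-out data
#'
#' @param model a \code{forest_model}
#' @param test data frame with the response and the model's features
#' @param response response column
#' @return an \code{eval_report}: 3x3 \code{confusion} (rows = true class,
#'   fixed order car, bicycle, walk), \code{accuracy} and per-class
#'   \code{recall}
#' @export
evaluate_forest <- function(model, test, response = "mode") {
  votes <- predict_votes(model, test)
  pred <- factor(model$classes[max.col(votes, ties.method = "first")], levels = model$classes)
  truth <- factor(test[[response]], levels = model$classes)
  cm <- table(true = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  rec <- diag(cm) / pmax(1, rowSums(cm))
  structure(list(confusion = unclass(cm), accuracy = acc, recall = rec),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}
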