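# Pruning, rebalancing, splitting, tuning, training and evaluation.

test_that("correlation pruning drops one of an identical pair and keeps independents", {
  set.seed(1)
  x <- rnorm(1e4)
  tab <- data.frame(a = x, b = x, mode = "car")           # r = 1
  expect_equal(length(prune_correlated(tab)), 1)
  tab2 <- data.frame(a = rnorm(1e4), b = rnorm(1e4), mode = "car")
  expect_setequal(prune_correlated(tab2), c("a", "b"))    # independent normals
  tab3 <- data.frame(a = rnorm(100), k = 1, mode = "car")
  expect_warning(prune_correlated(tab3), class = "routexpose_warning")
})

test_that("keep-list forces the retained POI set under heavy POI correlation", {
  set.seed(2)
  base <- rnorm(2000)
  poi <- lapply(1:6, function(i) base + rnorm(2000, sd = 0.3))  # pairwise r ~ 0.9
  names(poi) <- c("mean_poi_educational", "mean_poi_recreational", "mean_poi_medical",
                  "mean_poi_public_services", "mean_poi_retail", "mean_poi_others")
  tab <- as.data.frame(poi)
  tab$distance_m <- rnorm(2000)
  tab$mode <- "car"
  kept <- prune_correlated(tab, keep = default_keep_list())
  expect_setequal(grep("^mean_poi_", kept, value = TRUE), default_keep_list())
  expect_true("distance_m" %in% kept)
})

test_that("near-miss equalises every class to the minority count", {
  set.seed(3)
  X <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  y <- rep(c("car", "bicycle", "walk"), times = c(10, 4, 6))
  out <- nearmiss_undersample(X, y)
  expect_true(all(table(out$y) == 4))
  expect_equal(nrow(out$X), 12)
  expect_true(all(which(y == "bicycle") %in% out$idx))    # minority untouched
  # already balanced: everything retained
  yb <- rep(c("car", "walk"), each = 5)
  outb <- nearmiss_undersample(X[1:10, ], yb)
  expect_equal(outb$idx, 1:10)
  yf <- factor(rep("car", 10), levels = c("car", "walk"))
  expect_error(nearmiss_undersample(X[1:10, ], yf), class = "routexpose_class_missing")
})

test_that("keep-closest retention matches a brute-force nearest-neighbour oracle", {
  set.seed(4)
  X <- data.frame(x1 = c(rnorm(20, 0), rnorm(5, 3)), x2 = c(rnorm(20, 0), rnorm(5, 3)))
  y <- rep(c("car", "walk"), times = c(20, 5))
  out <- nearmiss_undersample(X, y, variant = "keep-closest")
  expect_equal(out$idx, nearmiss_oracle_keep(X, y))
  # remove-closest keeps the complementary (farthest) majority points
  out2 <- nearmiss_undersample(X, y, variant = "remove-closest")
  expect_equal(length(intersect(out$idx, out2$idx)), 5)   # only the minority overlaps
})

test_that("stratified split is exhaustive, disjoint and seed-stable", {
  set.seed(5)
  tab <- data.frame(individual_id = 1:100, x = rnorm(100),
                    mode = rep(c("car", "bicycle", "walk"), times = c(50, 20, 30)))
  sp <- split_trips(tab, 0.3, seed = 42)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sort(c(sp$train$individual_id, sp$test$individual_id)), 1:100)
  expect_equal(as.numeric(table(sp$test$mode)[c("car", "bicycle", "walk")]),
               c(15, 6, 9))
  sp2 <- split_trips(tab, 0.3, seed = 42)
  expect_identical(sp$test$individual_id, sp2$test$individual_id)
  # 10 per class at 0.5 -> exactly 5 per class each side
  tab2 <- data.frame(x = rnorm(30), mode = rep(c("car", "bicycle", "walk"), each = 10))
  sp3 <- split_trips(tab2, 0.5, seed = 1)
  expect_true(all(table(sp3$train$mode) == 5))
  expect_true(all(table(sp3$test$mode) == 5))
  expect_error(split_trips(tab, 0), class = "routexpose_invalid_config")
})

test_that("tuning selects the single grid point, skips infeasible ones, and beats baseline", {
  blobs <- make_blobs(300, seed = 6)
  tn <- tune_forest(blobs, model_config(tree_grid = 50, max_features_grid = 2, seed = 1))
  expect_equal(tn$n_trees, 50)
  expect_equal(tn$max_features, 2)
  expect_equal(nrow(tn$grid), 1)
  expect_warning(
    tn2 <- tune_forest(blobs, model_config(tree_grid = 50, max_features_grid = c(1, 2, 99),
                                           seed = 1)),
    class = "routexpose_warning")
  expect_equal(nrow(tn2$grid), 2)                          # bookkeeping minus skipped
  # y depends only on x1: tuned model must beat the majority baseline
  set.seed(7)
  dep <- data.frame(x1 = rnorm(600), x2 = rnorm(600), x3 = rnorm(600))
  dep$mode <- ifelse(dep$x1 > 0, "car", "walk")
  tn3 <- tune_forest(dep, model_config(tree_grid = 50, max_features_grid = c(1, 2), seed = 1))
  expect_gte(max(tn3$grid$accuracy), max(table(dep$mode)) / nrow(dep))
})

test_that("forest training is seeded, votes form a simplex, separable data is learnt", {
  blobs <- make_blobs(3000, seed = 8)
  sp <- split_trips(blobs, 0.3, seed = 1)
  m1 <- train_forest(sp$train, n_trees = 100, max_features = 2, seed = 9)
  m2 <- train_forest(sp$train, n_trees = 100, max_features = 2, seed = 9)
  v <- predict_votes(m1, sp$test)
  expect_equal(unname(rowSums(v)), rep(1, nrow(v)), tolerance = 1e-12)
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(v, predict_votes(m2, sp$test))          # determinism
  ev <- evaluate_forest(m1, sp$test)
  expect_gt(ev$accuracy, 0.95)                             # linearly separable blobs
  expect_error(train_forest(sp$train, 0, 2), class = "routexpose_invalid_config")
  expect_error(predict_votes(m1, sp$test[, "x1", drop = FALSE]),
               class = "routexpose_schema")
})

test_that("the confusion matrix matches a brute-force tally", {
  blobs <- make_blobs(600, seed = 10, sd = 2.5)            # some confusion
  sp <- split_trips(blobs, 0.3, seed = 2)
  m <- train_forest(sp$train, 60, 2, seed = 3)
  ev <- evaluate_forest(m, sp$test)
  pred <- as.character(predict(m$rf, sp$test[m$features]))
  tally <- matrix(0L, 3, 3, dimnames = list(m$classes, m$classes))
  for (i in seq_len(nrow(sp$test)))
    tally[sp$test$mode[i], pred[i]] <- tally[sp$test$mode[i], pred[i]] + 1L
  expect_equal(unclass(ev$confusion), unclass(tally), ignore_attr = TRUE)
  expect_equal(ev$accuracy, sum(diag(tally)) / sum(tally))
  expect_equal(sum(ev$confusion), nrow(sp$test))
})

test_that("OOB and held-out accuracy agree on balanced data at n = 10^4", {
  gaps <- vapply(1:3, function(seed) {
    blobs <- make_blobs(10002, seed = seed, sd = 3)
    sp <- split_trips(blobs, 0.3, seed = seed)
    m <- train_forest(sp$train, 150, 1, seed = seed)
    ev <- evaluate_forest(m, sp$test)
    abs(m$oob_accuracy - ev$accuracy)
  }, 0)
  expect_lt(mean(gaps), 0.05)
})

test_that("label permutation drives accuracy to chance on balanced data", {
  blobs <- make_blobs(6000, seed = 11)
  set.seed(12)
  blobs$mode <- sample(blobs$mode)
  sp <- split_trips(blobs, 0.3, seed = 12)
  m <- train_forest(sp$train, 150, 1, seed = 12)
  ev <- evaluate_forest(m, sp$test)
  expect_lt(abs(ev$accuracy - 1 / 3), 0.03)
})

test_that("mode_forest runs the full protocol and exposes a model interface", {
  asm <- assemble_trips(small_run_config(seed = 5))
  fit <- suppressWarnings(mode_forest(asm$trips,
                                      model_config(n_trees_final = 80,
                                                   max_features_final = 3, seed = 2)))
  expect_s3_class(fit, "mode_forest")
  expect_true(all(table(fit$train$mode) == min(table(fit$train$mode))))
  expect_equal(fit$n_train + fit$n_test, nrow(asm$trips))
  expect_equal(dim(fit$eval$confusion), c(3, 3))
  expect_equal(rownames(fit$eval$confusion), c("car", "bicycle", "walk"))
  pr <- predict(fit, asm$trips[1:10, ], type = "vote")
  expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-12)
  expect_output(print(fit), "held-out accuracy")
})
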