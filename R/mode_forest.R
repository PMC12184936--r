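#' Fit a rebalanced, tuned random-forest mode-choice model
#'
#' One call runs the full modelling protocol on an individual-level trip
#' table: prune features whose pairwise |Pearson r| exceeds the threshold,
#' split 70/30 stratified by mode, rebalance the training partition to the
#' minority-class size by near-miss undersampling (the test partition keeps
#' the original class distribution), optionally grid-search (n_trees,
#' max_features) by 3-fold cross-validation, train the final forest, and
#' evaluate it on the held-out set -- both at the original class
#' distribution and on a rebalanced copy of the test set.
#'
#' @param data individual-level trip table with a \code{mode} column
#' @param config a \code{\link{model_config}}
#' @param response response column name (default \code{"mode"})
#' @return an object of class \code{mode_forest} with components
#'   \code{model} (the \code{forest_model}), \code{features} (retained after
#'   pruning), \code{tuning} (accuracy grid, NULL when tuning was skipped),
#'   \code{eval} and \code{eval_balanced} (\code{eval_report}s),
#'   \code{split} counts and the \code{config}
#' @seealso \code{\link{gini_importance}}, \code{\link{partial_dependence}}
#' @examples
#' \donttest{
#' city <- generate_city(city_config(seed = 1, n_buildings = 300, n_pois = 150))
#' flows <- generate_flows(city, utility_params(), n_flows = 250, seed = 1)
#' flows <- suppress_small_flows(flows)
#' grid <- make_grid(city$config$bbox)
#' grid <- aggregate_buildings(grid, city$buildings)
#' grid <- aggregate_streets(grid, city$streets)
#' grid <- count_pois(grid, city$pois)
#' grid <- assign_noise(grid, city$noise, city$scheme)
#' net <- build_network(city$streets)
#' trips <- build_trip_table(city, grid, net, flows)
#' fit <- mode_forest(trips, model_config(n_trees_final = 100,
#'                                        max_features_final = 3))
#' summary(fit)
#' }
#' @export
mode_forest <- function(data, config = model_config(), response = "mode") {
  feats <- prune_correlated(data, threshold = config$correlation_threshold,
                            keep = config$keep_list, response = response)
  sp <- split_trips(data, test_fraction = config$test_fraction,
                    seed = derive_seed(config$seed, 11L), response = response)
  bal <- nearmiss_undersample(sp$train[feats], sp$train[[response]],
                              variant = config$nearmiss_variant)
  train <- cbind(bal$X, stats::setNames(data.frame(as.character(bal$y)), response))

  tuning <- NULL
  if (is.null(config$n_trees_final) || is.null(config$max_features_final)) {
    tuning <- tune_forest(train, config, response = response)
    n_trees <- tuning$n_trees
    max_features <- tuning$max_features
  } else {
    n_trees <- config$n_trees_final
    max_features <- config$max_features_final
  }
  model <- train_forest(train, n_trees, max_features,
                        seed = derive_seed(config$seed, 12L), response = response)
  ev <- evaluate_forest(model, sp$test, response = response)
  tbal <- nearmiss_undersample(sp$test[feats], sp$test[[response]],
                               variant = config$nearmiss_variant)
  test_bal <- cbind(tbal$X, stats::setNames(data.frame(as.character(tbal$y)), response))
  ev_bal <- evaluate_forest(model, test_bal, response = response)

  structure(list(model = model, features = feats, tuning = tuning,
                 eval = ev, eval_balanced = ev_bal,
                 n_train = nrow(sp$train), n_train_balanced = nrow(train),
                 n_test = nrow(sp$test), config = config,
                 train = train, test = sp$test, test_balanced = test_bal,
                 response = response),
            class = "mode_forest")
}

#' @export
print.mode_forest <- function(x, ...) {
  cat("Rebalanced random-forest mode-choice model\n")
  cat(sprintf("  features: %d retained after pruning (|r| <= %.2f)\n",
              length(x$features), x$config$correlation_threshold))
  cat(sprintf("  train: %d rows -> %d after near-miss (%s); test: %d rows\n",
              x$n_train, x$n_train_balanced, x$config$nearmiss_variant, x$n_test))
  cat(sprintf("  forest: %d trees, %d features/split; OOB accuracy %.3f\n",
              x$model$n_trees, x$model$max_features, x$model$oob_accuracy))
  cat(sprintf("  held-out accuracy %.3f (original distribution), %.3f (rebalanced)\n",
              x$eval$accuracy, x$eval_balanced$accuracy))
  invisible(x)
}

#' @export
summary.mode_forest <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (held-out, original distribution):\n")
  print(object$eval$confusion)
  if (!is.null(object$tuning)) {
    cat("\nTuning grid (3-fold CV accuracy):\n")
    print(object$tuning$grid)
  }
  cat("\nTop importances:\n")
  print(utils::head(gini_importance(object), 5))
  invisible(object)
}

#' @export
predict.mode_forest <- function(object, newdata, type = c("class", "vote"), ...) {
  type <- match.arg(type)
  votes <- predict_votes(object$model, newdata)
  if (type == "vote") return(votes)
  factor(object$model$classes[max.col(votes, ties.method = "first")],
         levels = object$model$classes)
}

#' @export
plot.mode_forest <- function(x, ...) {
  imp <- gini_importance(x)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, xlab = "Gini importance (normalised)",
                    main = "Variable importance", ...)
  invisible(x)
}
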