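# Model interpretation: Gini (mean decrease impurity) variable importance
# and multiclass partial dependence on the log-of-votes scale.

#' Normalised Gini variable importance
#'
#' The mean decrease in Gini impurity attributed to each feature across the
#' ensemble, normalised to sum to 1. Rank order is descending, with exact
#' ties broken by feature name.
#'
#' @param model a \code{forest_model} or \code{mode_forest}
#' @return data frame (feature, importance, rank) sorted by rank
#' @export
gini_importance <- function(model) {
  if (inherits(model, "mode_forest")) model <- model$model
  if (!inherits(model, "forest_model") || is.null(model$rf))
    rx_stop("state", "model is not a fitted forest")
  imp <- model$rf$importance[, "MeanDecreaseGini", drop = FALSE]
  imp <- stats::setNames(as.numeric(imp), rownames(imp))
  if (sum(imp) <= 0) rx_stop("state", "ensemble has no recorded impurity decrease")
  imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  out <- data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
                    rank = seq_along(imp))
  rownames(out) <- NULL
  out
}

#' Log-of-votes partial-dependence transform
#'
#' Maps per-class vote fractions to the partial-dependence scale. The
#' \code{"printed"} variant is
#' \deqn{f_k = \log p_k - \sum_{j=1}^{K} \log p_j,}
#' the \code{"centered"} variant subtracts the mean instead,
#' \deqn{f_k = \log p_k - \frac{1}{K}\sum_{j=1}^{K} \log p_j,}
#' which is the conventional multiclass logit centring and sums to zero
#' across classes at every point.
#'
#' @param p vote-fraction vector, or matrix with one row per observation
#'   (rows on the probability simplex, strictly positive)
#' @param variant \code{"centered"} (default) or \code{"printed"}
#' @return same shape as \code{p}, on the partial-dependence scale
#' @export
vote_logits <- function(p, variant = c("centered", "printed")) {
  variant <- match.arg(variant)
  m <- if (is.matrix(p)) p else matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  if (any(m <= 0)) rx_stop("numerical_guard", "vote fractions must be strictly positive")
  lg <- log(m)
  s <- rowSums(lg)
  out <- if (variant == "printed") lg - s else lg - s / ncol(m)
  if (is.matrix(p)) out else out[1, ]
}

#' Multiclass partial dependence of the mode forest on one feature
#'
#' Evaluates the model's response over \code{n_grid} evenly spaced values
#' between the feature's 1st and 99th percentiles, with two probe
#' strategies:
#' \itemize{
#'   \item \code{probe = "means"}: a single probe row per grid value, every
#'     other feature held at its mean over \code{X} (the held-at-means
#'     protocol). Note the mean noise-share vector need not lie on the
#'     probability simplex; \code{renormalize_shares = TRUE} rescales it.
#'   \item \code{probe = "average"}: the Friedman partial-dependence
#'     estimator -- clone (a deterministic, evenly spaced subsample of)
#'     \code{X}, overwrite the feature column with the grid value, and
#'     average the per-class vote fractions over rows. Statistically much
#'     more stable, since single-row vote fractions from a finite ensemble
#'     are step functions.
#' }
#' In both cases the (averaged) vote fractions are smoothed as
#' \eqn{(v_j + \epsilon)/(\sum v + K\epsilon)} with
#' \eqn{\epsilon = 1/(2\,n_{trees})} (zero-vote classes occur on probe
#' rows) and mapped through \code{\link{vote_logits}}.
#'
#' @param model a \code{forest_model} or \code{mode_forest}
#' @param X data table the means, percentiles and background rows are taken
#'   over (defaults to the training table of a \code{mode_forest})
#' @param feature feature name
#' @param n_grid number of grid points (default 50)
#' @param variant \code{"centered"} (default) or \code{"printed"}
#' @param probe \code{"means"} (default) or \code{"average"}
#' @param n_background rows averaged over for \code{probe = "average"}
#'   (evenly spaced subsample of \code{X}; default 1000)
#' @param renormalize_shares rescale probe noise-share columns to the
#'   simplex (\code{probe = "means"} only)
#' @return a \code{pdp_result} data frame (feature, grid_value, class, f,
#'   variant)
#' @export
partial_dependence <- function(model, X = NULL, feature, n_grid = 50,
                               variant = c("centered", "printed"),
                               probe = c("means", "average"),
                               n_background = 1000,
                               renormalize_shares = FALSE) {
  variant <- match.arg(variant)
  probe <- match.arg(probe)
  if (inherits(model, "mode_forest")) {
    if (is.null(X)) X <- model$train
    model <- model$model
  }
  if (is.null(X)) rx_stop("invalid_config", "X is required for a bare forest_model")
  if (!(feature %in% model$features))
    rx_stop("schema", sprintf("'%s' is not a training feature", feature))
  qs <- stats::quantile(X[[feature]], c(0.01, 0.99), names = FALSE)
  if (!(qs[2] > qs[1]))
    rx_stop("invalid_config", sprintf("feature '%s' is degenerate on [p1, p99]", feature))
  grid <- seq(qs[1], qs[2], length.out = n_grid)
  eps <- 1 / (2 * model$n_trees)
  if (probe == "means") {
    mu <- vapply(model$features, function(f) mean(X[[f]]), 0)
    pr <- as.data.frame(matrix(rep(mu, each = n_grid), nrow = n_grid,
                               dimnames = list(NULL, model$features)))
    if (renormalize_shares) {
      sc <- grep("^noise_share_", model$features, value = TRUE)
      if (length(sc) && !(feature %in% sc)) {
        tot <- sum(mu[sc])
        if (tot > 0) pr[sc] <- pr[sc] / tot
      }
    }
    pr[[feature]] <- grid
    v <- predict_votes(model, pr)
  } else {
    nb <- min(n_background, nrow(X))
    bg <- X[unique(round(seq(1, nrow(X), length.out = nb))), model$features, drop = FALSE]
    big <- bg[rep(seq_len(nrow(bg)), times = n_grid), , drop = FALSE]
    big[[feature]] <- rep(grid, each = nrow(bg))
    vv <- predict_votes(model, big)
    gidx <- rep(seq_len(n_grid), each = nrow(bg))
    v <- apply(vv, 2, function(col) tapply(col, gidx, mean))
  }
  K <- ncol(v)
  p <- (v + eps) / (rowSums(v) + K * eps)
  if (any(p <= 0)) rx_stop("numerical_guard", "vote fraction not positive after smoothing")
  f <- vote_logits(p, variant)
  out <- data.frame(feature = feature,
                    grid_value = rep(grid, times = K),
                    class = rep(colnames(v), each = n_grid),
                    f = as.numeric(f),
                    variant = variant,
                    probe = probe)
  class(out) <- c("pdp_result", "data.frame")
  out
}

#' @export
plot.pdp_result <- function(x, ...) {
  classes <- unique(x$class)
  grid <- unique(x$grid_value)
  m <- sapply(classes, function(cl) x$f[x$class == cl])
  graphics::matplot(grid, m, type = "l", lty = 1, lwd = 2,
                    col = seq_along(classes),
                    xlab = unique(x$feature), ylab = "partial dependence (log votes)",
                    main = sprintf("Partial dependence (%s variant)", unique(x$variant)), ...)
  graphics::legend("topright", legend = classes, col = seq_along(classes), lwd = 2, bty = "n")
  invisible(x)
}

#' Tidy export helpers for interpretation outputs
#'
#' @param x an importance table or \code{pdp_result}
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_importance_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_importance_csv
#' @export
write_pdp_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
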