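# Shared fixtures, all generated in code at test time.

# A small city: quick to generate, grid, route.
small_city_config <- function(seed = 11, n_arterials = 2) {
  city_config(bbox = c(0, 0, 2500, 2500), n_arterials = n_arterials,
              n_local_roads = 180, n_buildings = 300, n_pois = 160,
              poi_cluster_centers = 5, seed = seed)
}

small_run_config <- function(seed = 5, n_flows = 250) {
  run_config(city = small_city_config(),
             model = model_config(n_trees_final = 80, max_features_final = 3),
             n_flows = n_flows, seed = seed)
}

# Brute-force shortest path by exhaustive simple-path enumeration (DFS).
# edges: data.frame(from, to, length); undirected. Returns Inf if no path.
enumerate_shortest <- function(edges, from, to) {
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) return(invisible())
    if (node == to) { best <<- len; return(invisible()) }
    nb <- rbind(edges[edges$from == node, c("to", "length")],
                stats::setNames(edges[edges$to == node, c("from", "length")],
                                c("to", "length")))
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (!(v %in% visited)) recurse(v, c(visited, v), len + nb$length[i])
    }
  }
  recurse(from, from, 0)
  best
}

# 3-class Gaussian blobs: linearly separable when sep is large.
make_blobs <- function(n, sep = 6, sd = 1, seed = 1, p_noise = 0) {
  stopifnot(n %% 3 == 0)
  set.seed(seed)
  k <- n / 3
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(k, centers[i, 1], sd), rnorm(k, centers[i, 2], sd))))
  df <- data.frame(x1 = X[, 1], x2 = X[, 2])
  if (p_noise > 0) for (j in seq_len(p_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  df$mode <- rep(c("car", "bicycle", "walk"), each = k)
  df
}

# Literal double-loop near-miss oracle (keep-closest): which majority rows
# survive, by mean distance to the k nearest minority rows on z-scored X.
nearmiss_oracle_keep <- function(X, y, k = 3) {
  X <- as.matrix(X)
  mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  keep <- which(y == minority)
  for (cl in setdiff(levels(factor(y)), minority)) {
    rows <- which(y == cl)
    if (length(rows) <= n_min) { keep <- c(keep, rows); next }
    md <- sapply(rows, function(i) {
      d <- sapply(which(y == minority), function(j) sqrt(sum((Z[i, ] - Z[j, ])^2)))
      mean(sort(d)[seq_len(min(k, length(d)))])
    })
    keep <- c(keep, rows[order(md, rows)][seq_len(n_min)])
  }
  sort(keep)
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(actual - expected), tol * max(1, abs(expected)))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
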