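# Origin-destination commuting flows with mode labels drawn from a known
# multinomial-utility model. The utility model is the generator's ground
# truth: downstream tests check that the classifier and its interpretation
# recover its drivers (distance penalties, built-environment effects),
# not any numeric value from a real city.

MODES <- c("car", "bicycle", "walk")

#' Mode-utility parameters of the flow generator
#'
#' Each mode's utility on an OD pair is
#' \deqn{U_m = \beta_0 + \beta_d d + \beta_b B + \beta_p P + \beta_n N}
#' with \eqn{d} the straight-line OD distance in km, \eqn{B} the building
#' area within 300 m of the origin (in hectares), \eqn{P} the POI count
#' within 300 m of the origin, and \eqn{N} the noise proximity of the
#' straight OD corridor (mean of \eqn{e^{-d_a/200}} over points sampled
#' every 100 m, \eqn{d_a} = distance to the nearest arterial; 0 without
#' arterials). The mode is sampled from softmax(\eqn{U/\tau}).
#'
#' Defaults encode the behaviour the analysis should recover: walking is
#' heavily penalised by distance (and mildly deterred by corridor noise),
#' cycling sits between walking and driving and tolerates noisy corridors,
#' driving is the distance-insensitive reference, so cars dominate overall.
#'
#' @param car,bicycle,walk numeric length-5 coefficient vectors
#'   (intercept, distance per km, building density, POI count, noise
#'   proximity)
#' @param temperature softmax temperature, must be > 0
#' @return a \code{utility_params} object
#' @export
utility_params <- function(car = c(0, 0, 0, 0, 0),
                           bicycle = c(-0.4, -0.25, 0.05, 0.02, 0.3),
                           walk = c(2.6, -2.0, 0.10, 0.03, -0.4),
                           temperature = 1) {
  if (length(car) != 5L || length(bicycle) != 5L || length(walk) != 5L)
    rx_stop("invalid_params", "each mode needs 5 coefficients")
  coefs <- rbind(car = car, bicycle = bicycle, walk = walk)
  if (!all(is.finite(coefs)))
    rx_stop("invalid_params", "coefficients must be finite")
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    rx_stop("invalid_params", "temperature must be > 0")
  colnames(coefs) <- c("intercept", "dist_km", "building_density", "poi_count", "noise_proximity")
  structure(list(coefs = coefs, temperature = temperature), class = "utility_params")
}

# Origin-neighbourhood and corridor covariates for a set of OD pairs.
flow_covariates <- function(city, origins, dests, radius = 300) {
  n <- nrow(origins)
  dist_km <- sqrt(rowSums((dests - origins)^2)) / 1000
  bdens <- numeric(n); poi <- numeric(n)
  bc <- city$building_centroids; ba <- city$building_areas
  px <- if (nrow(city$pois)) cbind(city$pois$x, city$pois$y) else matrix(numeric(0), ncol = 2)
  chunk <- 2000L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    o <- origins[lo:hi, , drop = FALSE]
    if (length(ba)) {
      d2 <- outer(o[, 1], bc[, 1], "-")^2 + outer(o[, 2], bc[, 2], "-")^2
      bdens[lo:hi] <- as.numeric((d2 <= radius^2) %*% ba) / 1e4
    }
    if (nrow(px)) {
      d2 <- outer(o[, 1], px[, 1], "-")^2 + outer(o[, 2], px[, 2], "-")^2
      poi[lo:hi] <- rowSums(d2 <= radius^2)
    }
  }
  art <- as.matrix(city$streets[city$streets$class == "arterial",
                                c("x1", "y1", "x2", "y2"), drop = FALSE])
  noisep <- numeric(n)
  if (nrow(art)) {
    for (i in seq_len(n)) {
      L <- max(1e-9, dist_km[i] * 1000)
      m <- max(2L, ceiling(L / 100) + 1L)
      t <- seq(0, 1, length.out = m)
      pts <- cbind(origins[i, 1] + t * (dests[i, 1] - origins[i, 1]),
                   origins[i, 2] + t * (dests[i, 2] - origins[i, 2]))
      noisep[i] <- mean(exp(-dist_points_segments(pts, art) / 200))
    }
  }
  data.frame(dist_km = dist_km, building_density = bdens, poi_count = poi,
             noise_proximity = noisep)
}

#' Generate mode-labelled OD commuting flows
#'
#' Origins are uniform in the bbox; destinations are drawn towards the city
#' centre (workplaces cluster centrally). Each flow's mode is sampled from
#' the softmax of the three mode utilities on that OD pair; commuter counts
#' follow a shifted geometric distribution (1 + Geom), so both suppressed
#' and retained flows occur under the census privacy rule.
#'
#' @param city a \code{\link{generate_city}} result
#' @param params a \code{\link{utility_params}}
#' @param n_flows number of flows to draw (>= 1)
#' @param seed integer seed
#' @param count_mean mean commuter count per flow (default 15)
#' @return data frame with columns \code{origin_x, origin_y, dest_x,
#'   dest_y, mode, count}
#' @export
generate_flows <- function(city, params, n_flows, seed, count_mean = 15) {
  if (!inherits(params, "utility_params"))
    rx_stop("invalid_params", "params must come from utility_params()")
  n_flows <- check_count(n_flows, "n_flows", min = 1L)
  if (count_mean < 1) rx_stop("invalid_params", "count_mean must be >= 1")
  bbox <- city$config$bbox
  with_seed(seed, {
    ox <- stats::runif(n_flows, bbox[1], bbox[3])
    oy <- stats::runif(n_flows, bbox[2], bbox[4])
    cx0 <- mean(bbox[c(1, 3)]); cy0 <- mean(bbox[c(2, 4)])
    dx <- pmin(bbox[3], pmax(bbox[1], stats::rnorm(n_flows, cx0, (bbox[3] - bbox[1]) / 6)))
    dy <- pmin(bbox[4], pmax(bbox[2], stats::rnorm(n_flows, cy0, (bbox[4] - bbox[2]) / 6)))
    origins <- cbind(ox, oy); dests <- cbind(dx, dy)
    cov <- flow_covariates(city, origins, dests)
    U <- params$coefs %*% t(cbind(1, cov$dist_km, cov$building_density,
                                  cov$poi_count, cov$noise_proximity))
    U <- U / params$temperature
    U <- sweep(U, 2, apply(U, 2, max))       # softmax stabilisation
    P <- exp(U); P <- sweep(P, 2, colSums(P), "/")
    u <- stats::runif(n_flows)
    cum <- apply(P, 2, cumsum)
    mode_idx <- 1L + colSums(cum < rep(u, each = 3L))
    counts <- 1L + stats::rgeom(n_flows, prob = 1 / count_mean)
    data.frame(origin_x = ox, origin_y = oy, dest_x = dx, dest_y = dy,
               mode = MODES[mode_idx], count = as.integer(counts))
  })
}

#' Suppress small flows (census privacy rule)
#'
#' Drops OD records with fewer than \code{threshold} commuters, preserving
#' the order of the remaining rows.
#'
#' @param flows data frame with a \code{count} column
#' @param threshold minimum retained count (default 10)
#' @return the filtered data frame
#' @examples
#' f <- data.frame(origin_x = 0, origin_y = 0, dest_x = 1, dest_y = 1,
#'                 mode = "car", count = c(12, 9, 10))
#' suppress_small_flows(f)$count  # 12, 10
#' @export
suppress_small_flows <- function(flows, threshold = 10) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    rx_stop("invalid_config", "threshold must be a single number >= 0")
  out <- flows[flows$count >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
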