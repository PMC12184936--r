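# Synthetic city generator.
#
# The generator is a first-class, documented stand-in for the real data this
# kind of analysis consumes (census origin-destination flows, strategic
# road-traffic noise maps, building footprints, road centrelines, points of
# interest). Its purpose is to provide ground truth: mode labels are drawn
# from a known multinomial-utility model, so the downstream classifier and
# its interpretation can be validated by parameter recovery instead of by
# reproducing any real-city figure.

#' Configuration of a synthetic city
#'
#' @param bbox planar rectangle \code{c(xmin, ymin, xmax, ymax)} in metres
#' @param n_arterials number of high-noise major road corridors (lattice
#'   rows upgraded to arterial class)
#' @param n_local_roads approximate number of local street segments; sets
#'   the density of the jittered street lattice
#' @param n_buildings number of building footprints (axis-aligned
#'   rectangles, centre-weighted density gradient)
#' @param n_pois number of points of interest
#' @param poi_cluster_centers number of POI cluster centres
#' @param poi_categories ordered category labels (default the six of
#'   \code{\link{poi_categories}})
#' @param noise_scheme_name a built-in \code{\link{noise_scheme}} name
#' @param noise_tile_m side length of the square tiles that partition the
#'   bbox into noise polygons (metres)
#' @param noise_radii ascending distances (m) from the nearest arterial that
#'   bound each noise band, loudest innermost; default is a geometric ladder
#'   starting at 60 m with ratio 2.2
#' @param seed integer seed; identical config and seed give byte-identical
#'   output
#' @return a validated \code{city_config} list
#' @export
city_config <- function(bbox = c(0, 0, 4000, 4000),
                        n_arterials = 3,
                        n_local_roads = 480,
                        n_buildings = 1500,
                        n_pois = 600,
                        poi_cluster_centers = 8,
                        poi_categories = routexpose::poi_categories(),
                        noise_scheme_name = "london6",
                        noise_tile_m = 50,
                        noise_radii = NULL,
                        seed = 1) {
  bbox <- check_bbox(bbox)
  cfg <- list(
    bbox = bbox,
    n_arterials = check_count(n_arterials, "n_arterials"),
    n_local_roads = check_count(n_local_roads, "n_local_roads"),
    n_buildings = check_count(n_buildings, "n_buildings"),
    n_pois = check_count(n_pois, "n_pois"),
    poi_cluster_centers = check_count(poi_cluster_centers, "poi_cluster_centers"),
    poi_categories = as.character(poi_categories),
    noise_scheme_name = noise_scheme_name,
    noise_tile_m = as.numeric(noise_tile_m),
    seed = check_count(seed, "seed")
  )
  scheme <- noise_scheme(noise_scheme_name)
  K <- n_classes(scheme)
  if (is.null(noise_radii)) noise_radii <- 60 * 2.2^(0:(K - 2))
  if (length(noise_radii) != K - 1L || is.unsorted(noise_radii, strictly = TRUE))
    rx_stop("invalid_config", "noise_radii must be strictly ascending with one radius per class boundary")
  cfg$noise_radii <- as.numeric(noise_radii)
  if (cfg$noise_tile_m <= 0) rx_stop("invalid_config", "noise_tile_m must be positive")
  class(cfg) <- "city_config"
  cfg
}

#' Generate a synthetic city
#'
#' Produces four layers inside the configured bbox:
#' \itemize{
#'   \item \code{streets}: a jittered lattice of segments, noded at shared
#'     endpoints, classed \code{arterial} (selected full-width corridors) or
#'     \code{local};
#'   \item \code{buildings}: rectangular footprints with density decaying
#'     from the centre;
#'   \item \code{pois}: categorised points clustered around a few centres;
#'   \item \code{noise}: square tiles that exactly partition the bbox, each
#'     carrying the ordinal class of its centre's distance-to-arterial band
#'     (loudest nearest, quietest beyond the last radius; the lowest class
#'     everywhere when there are no arterials).
#' }
#'
#' @param config a \code{\link{city_config}}
#' @return a \code{synthetic_city}: list with \code{config}, \code{streets}
#'   (segment data frame \code{x1,y1,x2,y2,class}), \code{buildings} (list
#'   of polygons), \code{building_centroids}, \code{building_areas},
#'   \code{pois} (data frame \code{x,y,category}), \code{noise} (list of
#'   \code{polygons}, \code{class}, \code{extent}), and \code{scheme}
#' @export
generate_city <- function(config) {
  if (!inherits(config, "city_config")) config <- do.call(city_config, config)
  bbox <- config$bbox
  w <- bbox[3] - bbox[1]; h <- bbox[4] - bbox[2]
  scheme <- noise_scheme(config$noise_scheme_name)

  streets <- with_seed(derive_seed(config$seed, 1L), gen_streets(config))
  buildings <- with_seed(derive_seed(config$seed, 2L), gen_buildings(config))
  pois <- with_seed(derive_seed(config$seed, 3L), gen_pois(config))
  noise <- gen_noise(config, streets, scheme)  # deterministic given streets

  city <- list(config = config, streets = streets,
               buildings = buildings$polys,
               building_centroids = buildings$centroids,
               building_areas = buildings$areas,
               pois = pois, noise = noise, scheme = scheme)
  class(city) <- "synthetic_city"
  city
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("synthetic_city: %d street segments (%d arterial), %d buildings, %d POIs, %d noise tiles\n",
              nrow(x$streets), sum(x$streets$class == "arterial"),
              length(x$buildings), nrow(x$pois), length(x$noise$polygons)))
  invisible(x)
}

gen_streets <- function(config) {
  bbox <- config$bbox
  # lattice size k x k so that total edge count 2k(k-1) ~ n_local_roads
  k <- max(2L, as.integer(round((1 + sqrt(1 + 2 * config$n_local_roads)) / 2)))
  xs <- seq(bbox[1], bbox[3], length.out = k)
  ys <- seq(bbox[2], bbox[4], length.out = k)
  sp <- min(diff(xs)[1], diff(ys)[1])
  jit <- 0.2 * sp
  nx <- matrix(0, k, k); ny <- matrix(0, k, k)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    nx[i, j] <- min(bbox[3], max(bbox[1], xs[i] + stats::runif(1, -jit, jit)))
    ny[i, j] <- min(bbox[4], max(bbox[2], ys[j] + stats::runif(1, -jit, jit)))
  }
  art_rows <- integer(0)
  if (config$n_arterials > 0) {
    if (config$n_arterials > k)
      rx_stop("invalid_config", "more arterials than lattice rows; increase n_local_roads")
    rows_seq <- round(seq(1, k, length.out = config$n_arterials + 2))
    art_rows <- unique(rows_seq[-c(1, length(rows_seq))])
  }
  rows <- vector("list", 2L * k * (k - 1L)); m <- 0L
  for (j in seq_len(k)) for (i in seq_len(k - 1L)) {   # horizontal edges
    m <- m + 1L
    rows[[m]] <- data.frame(x1 = nx[i, j], y1 = ny[i, j], x2 = nx[i + 1, j], y2 = ny[i + 1, j],
                            class = if (j %in% art_rows) "arterial" else "local")
  }
  for (j in seq_len(k - 1L)) for (i in seq_len(k)) {   # vertical edges
    m <- m + 1L
    rows[[m]] <- data.frame(x1 = nx[i, j], y1 = ny[i, j], x2 = nx[i, j + 1], y2 = ny[i, j + 1],
                            class = "local")
  }
  st <- do.call(rbind, rows[seq_len(m)])
  st$edge_id <- seq_len(nrow(st))
  st
}

gen_buildings <- function(config) {
  n <- config$n_buildings
  if (n == 0L) return(list(polys = list(), centroids = matrix(numeric(0), ncol = 2), areas = numeric(0)))
  bbox <- config$bbox
  w <- bbox[3] - bbox[1]; h <- bbox[4] - bbox[2]
  cx0 <- mean(bbox[c(1, 3)]); cy0 <- mean(bbox[c(2, 4)])
  inset <- 30
  central <- stats::runif(n) < 0.7   # density gradient: most mass near the centre
  px <- ifelse(central, stats::rnorm(n, cx0, w / 5), stats::runif(n, bbox[1], bbox[3]))
  py <- ifelse(central, stats::rnorm(n, cy0, h / 5), stats::runif(n, bbox[2], bbox[4]))
  px <- pmin(bbox[3] - inset, pmax(bbox[1] + inset, px))
  py <- pmin(bbox[4] - inset, pmax(bbox[2] + inset, py))
  bw <- stats::runif(n, 10, 40); bh <- stats::runif(n, 10, 40)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- max(bbox[1], px[i] - bw[i] / 2); x1 <- min(bbox[3], px[i] + bw[i] / 2)
    y0 <- max(bbox[2], py[i] - bh[i] / 2); y1 <- min(bbox[4], py[i] + bh[i] / 2)
    polys[[i]] <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  }
  list(polys = polys, centroids = cbind(px, py),
       areas = vapply(polys, poly_area, 0))
}

gen_pois <- function(config) {
  n <- config$n_pois
  cats <- config$poi_categories
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0), category = character(0)))
  bbox <- config$bbox
  nc <- max(1L, config$poi_cluster_centers)
  ctr <- cbind(stats::runif(nc, bbox[1] + 200, bbox[3] - 200),
               stats::runif(nc, bbox[2] + 200, bbox[4] - 200))
  cl <- sample.int(nc, n, replace = TRUE)
  x <- pmin(bbox[3], pmax(bbox[1], ctr[cl, 1] + stats::rnorm(n, 0, 150)))
  y <- pmin(bbox[4], pmax(bbox[2], ctr[cl, 2] + stats::rnorm(n, 0, 150)))
  # category mix: retail-heavy, as in commercial OSM extracts
  probs <- c(0.12, 0.18, 0.08, 0.12, 0.30, 0.20)
  if (length(cats) != 6L) probs <- rep(1 / length(cats), length(cats))
  category <- sample(cats, n, replace = TRUE, prob = probs)
  data.frame(x = x, y = y, category = category)
}

gen_noise <- function(config, streets, scheme) {
  bbox <- config$bbox
  K <- n_classes(scheme)
  art <- streets[streets$class == "arterial", c("x1", "y1", "x2", "y2"), drop = FALSE]
  nx <- max(1L, ceiling((bbox[3] - bbox[1]) / config$noise_tile_m))
  ny <- max(1L, ceiling((bbox[4] - bbox[2]) / config$noise_tile_m))
  xb <- seq(bbox[1], bbox[3], length.out = nx + 1L)
  yb <- seq(bbox[2], bbox[4], length.out = ny + 1L)
  cxs <- (xb[-1] + xb[-(nx + 1L)]) / 2
  cys <- (yb[-1] + yb[-(ny + 1L)]) / 2
  centers <- cbind(rep(cxs, times = ny), rep(cys, each = nx))
  d <- dist_points_segments(centers, as.matrix(art))
  cls <- K - findInterval(d, config$noise_radii)
  cls[!is.finite(d)] <- 1L
  polys <- vector("list", nx * ny)
  idx <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    idx <- idx + 1L
    polys[[idx]] <- rbind(c(xb[i], yb[j]), c(xb[i + 1], yb[j]),
                          c(xb[i + 1], yb[j + 1]), c(xb[i], yb[j + 1]))
  }
  list(polygons = polys, class = as.integer(cls), extent = bbox)
}
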