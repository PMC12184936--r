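# Generator contracts: determinism, noise decay, flow behaviour.

test_that("invalid configurations are rejected", {
  expect_error(city_config(bbox = c(0, 0, 0, 100)), class = "routexpose_invalid_config")
  expect_error(city_config(n_buildings = -1), class = "routexpose_invalid_config")
  expect_error(utility_params(temperature = 0), class = "routexpose_invalid_params")
  expect_error(utility_params(car = c(1, 2)), class = "routexpose_invalid_params")
})

test_that("same config and seed give identical cities and flows", {
  cfg <- small_city_config(seed = 4)
  c1 <- generate_city(cfg)
  c2 <- generate_city(cfg)
  expect_identical(c1$streets, c2$streets)
  expect_identical(c1$buildings, c2$buildings)
  expect_identical(c1$pois, c2$pois)
  expect_identical(c1$noise$class, c2$noise$class)
  f1 <- generate_flows(c1, utility_params(), 100, seed = 8)
  f2 <- generate_flows(c2, utility_params(), 100, seed = 8)
  expect_identical(f1, f2)
})

test_that("without arterials every noise polygon carries the lowest class", {
  city <- generate_city(small_city_config(seed = 2, n_arterials = 0))
  expect_true(all(city$noise$class == 1L))
})

test_that("noise polygons partition the bbox and decay with arterial distance", {
  cfg <- city_config(bbox = c(0, 0, 4000, 4000), n_arterials = 2, n_local_roads = 180,
                     n_buildings = 100, n_pois = 50, seed = 7)
  city <- generate_city(cfg)
  areas <- vapply(city$noise$polygons, routexpose:::poly_area, 0)
  expect_rel_equal(sum(areas), 4000^2, tol = 1e-6)
  # exhaustive point-sampling oracle: class means near vs far from arterials
  set.seed(99)
  pts <- cbind(runif(4000, 0, 4000), runif(4000, 0, 4000))
  art <- as.matrix(city$streets[city$streets$class == "arterial",
                                c("x1", "y1", "x2", "y2")])
  d <- routexpose:::dist_points_segments(pts, art)
  # locate each point's tile by brute-force bbox containment
  bbs <- t(vapply(city$noise$polygons, function(p)
    c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])), numeric(4)))
  cls <- vapply(seq_len(nrow(pts)), function(i) {
    hit <- which(pts[i, 1] >= bbs[, 1] & pts[i, 1] < bbs[, 3] &
                   pts[i, 2] >= bbs[, 2] & pts[i, 2] < bbs[, 4])[1]
    city$noise$class[hit]
  }, 1L)
  expect_gt(mean(cls[d < 100]), mean(cls[d > 1000]))
  # class is monotone non-increasing in the tile centre's arterial distance
  centers <- t(vapply(city$noise$polygons, colMeans, numeric(2)))
  dc <- routexpose:::dist_points_segments(centers, art)
  ord <- order(dc, city$noise$class)
  expect_true(all(diff(city$noise$class[ord]) <= 0 | diff(dc[ord]) == 0))
})

test_that("an effectively infinite walk distance penalty kills walk flows", {
  city <- generate_city(small_city_config(seed = 4))
  p <- utility_params(walk = c(2.6, -1e6, 0.1, 0.03, -0.4))
  f <- generate_flows(city, p, 2000, seed = 3)
  dist_km <- sqrt((f$dest_x - f$origin_x)^2 + (f$dest_y - f$origin_y)^2) / 1000
  expect_equal(sum(f$mode == "walk" & dist_km > 0.01), 0)
})

test_that("symmetric utilities give one-third shares at large n", {
  city <- generate_city(small_city_config(seed = 4))
  same <- c(0.3, -0.5, 0.1, 0.02, 0.1)
  p <- utility_params(car = same, bicycle = same, walk = same)
  f <- generate_flows(city, p, 30000, seed = 12)
  shares <- table(f$mode) / nrow(f)
  expect_true(all(abs(shares - 1 / 3) < 0.01))
})

test_that("default utilities penalise walking distance and favour car for long trips", {
  city <- generate_city(small_city_config(seed = 4))
  f <- generate_flows(city, utility_params(), 2000, seed = 1)
  d <- sqrt((f$dest_x - f$origin_x)^2 + (f$dest_y - f$origin_y)^2)
  expect_lt(mean(d[f$mode == "walk"]), mean(d[f$mode == "car"]))
  # counts are positive integers from the shifted geometric
  expect_true(all(f$count >= 1))
  expect_true(all(f$mode %in% c("car", "bicycle", "walk")))
})

test_that("raising the walk distance penalty never raises the long-trip walk share", {
  city <- generate_city(small_city_config(seed = 4))
  base <- utility_params()
  harsher <- utility_params(walk = c(2.6, -3.0, 0.10, 0.03, -0.4))
  f1 <- generate_flows(city, base, 4000, seed = 6)
  f2 <- generate_flows(city, harsher, 4000, seed = 6)   # same seed stream
  d <- sqrt((f1$dest_x - f1$origin_x)^2 + (f1$dest_y - f1$origin_y)^2)
  top <- d >= quantile(d, 0.9)
  expect_lte(mean(f2$mode[top] == "walk"), mean(f1$mode[top] == "walk"))
})

test_that("small-flow suppression keeps exactly the counts at or above threshold", {
  f <- data.frame(origin_x = 1:3, origin_y = 0, dest_x = 0, dest_y = 0,
                  mode = "car", count = c(12, 9, 10))
  expect_equal(suppress_small_flows(f)$count, c(12, 10))
  expect_equal(suppress_small_flows(f, 0), f)
  set.seed(5)
  many <- data.frame(origin_x = 0, origin_y = 0, dest_x = 1, dest_y = 1,
                     mode = "walk", count = sample(1:20, 1000, replace = TRUE))
  expect_equal(nrow(suppress_small_flows(many, 10)), sum(many$count >= 10))
  expect_error(suppress_small_flows(many, -1), class = "routexpose_invalid_config")
})

test_that("city layers survive a GeoJSON round trip", {
  city <- generate_city(small_city_config(seed = 6))
  d <- file.path(tempfile(), "city")
  write_city_geojson(city, d)
  back <- read_city_geojson(d)
  expect_equal(back$streets$x1, city$streets$x1)
  expect_equal(back$streets$class, city$streets$class)
  expect_equal(length(back$buildings), length(city$buildings))
  expect_equal(back$buildings[[5]], unname(city$buildings[[5]]))
  expect_equal(back$pois$category, city$pois$category)
  expect_equal(back$noise$class, city$noise$class)
})
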