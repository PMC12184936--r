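# Tessellation, lookup and conservative aggregation.

test_that("built-in noise schemes match the published class bounds", {
  l6 <- noise_scheme("london6")
  expect_equal(n_classes(l6), 6)
  expect_equal(l6$lower, c(-Inf, 55, 60, 65, 70, 75))
  expect_equal(l6$upper, c(55, 60, 65, 70, 75, Inf))
  b5 <- noise_scheme("brisbane5")
  expect_equal(n_classes(b5), 5)
  expect_equal(b5$lower, c(-Inf, 58, 63, 68, 73))
  expect_error(noise_scheme("paris"), class = "routexpose_invalid_config")
  expect_error(noise_scheme("bad", labels = c("a", "b"), lower = c(0, 60), upper = c(50, 70)),
               class = "routexpose_invalid_config")
  p <- tempfile(fileext = ".json")
  write_noise_scheme(l6, p)
  expect_equal(read_noise_scheme(p)$upper, l6$upper)
})

test_that("hexagon edge length follows the closed-form area relation", {
  g <- make_grid(c(0, 0, 2000, 2000), cell_area = 250000)
  expect_equal(g$s, sqrt(2 * 250000 / (3 * sqrt(3))), tolerance = 1e-12)
  expect_equal(round(g$s, 2), 310.20)
  # every cell polygon has the configured area; congruence to 1e-9 relative
  areas <- vapply(g$polys, routexpose:::poly_area, 0)
  expect_true(all(abs(areas - 250000) < 1e-6 * 250000))
  expect_lt(diff(range(areas)) / 250000, 1e-9)
  expect_error(make_grid(c(0, 0, 100, 100), cell_area = 0),
               class = "routexpose_invalid_config")
  expect_error(make_grid(c(0, 0, 0, 100)), class = "routexpose_invalid_config")
})

test_that("grid covers the bbox: tiny bbox gets at least one full-size cell", {
  g <- make_grid(c(500, 500, 501, 501), cell_area = 250000)
  expect_gte(nrow(g$cells), 1)
  expect_false(anyNA(cell_for_points(g, rbind(c(500, 500), c(501, 501), c(500.5, 500.5)))))
})

test_that("cell clips partition the bbox exactly", {
  g <- make_grid(c(0, 0, 2000, 2000))
  rect <- rbind(c(0, 0), c(2000, 0), c(2000, 2000), c(0, 2000))
  parts <- vapply(g$polys, function(p) {
    cp <- routexpose:::clip_poly_convex(p, rect)
    if (is.null(cp)) 0 else routexpose:::poly_area(cp)
  }, 0)
  expect_rel_equal(sum(parts), 4e6, tol = 1e-6)
})

test_that("building aggregation conserves area, splitting across cells", {
  g <- make_grid(c(0, 0, 2000, 2000))
  cid <- cell_for_points(g, rbind(c(1000, 1000)))
  j <- match(cid, g$cells$cell_id)
  cx <- g$cells$cx[j]; cy <- g$cells$cy[j]
  b <- rbind(c(cx - 5, cy - 10), c(cx + 5, cy - 10), c(cx + 5, cy), c(cx - 5, cy))
  g1 <- aggregate_buildings(g, list(b))
  expect_equal(g1$cells$building_area[j], 100)
  expect_equal(sum(g1$cells$building_area), 100)
  # rectangle centred on the shared vertical edge splits exactly 50/50
  ex <- cx + sqrt(3) / 2 * g$s
  b2 <- rbind(c(ex - 10, cy - 5), c(ex + 10, cy - 5), c(ex + 10, cy + 5), c(ex - 10, cy + 5))
  g2 <- aggregate_buildings(g, list(b2))
  touched <- which(g2$cells$building_area > 0)
  expect_length(touched, 2)
  expect_equal(g2$cells$building_area[touched], c(100, 100), tolerance = 1e-9)
  expect_error(aggregate_buildings(g, rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               class = "routexpose_geometry")
})

test_that("random rectangles aggregate with total-area conservation", {
  g <- make_grid(c(0, 0, 2000, 2000))
  set.seed(42)
  rects <- lapply(1:200, function(i) {
    x <- runif(1, 50, 1800); y <- runif(1, 50, 1800)
    w <- runif(1, 5, 150); h <- runif(1, 5, 150)
    rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h))
  })
  g2 <- aggregate_buildings(g, rects)
  expect_rel_equal(sum(g2$cells$building_area),
                   sum(vapply(rects, routexpose:::poly_area, 0)), tol = 1e-6)
})

test_that("street aggregation conserves length and splits at cell boundaries", {
  g <- make_grid(c(0, 0, 2000, 2000))
  cid <- cell_for_points(g, rbind(c(1000, 1000)))
  j <- match(cid, g$cells$cell_id)
  cx <- g$cells$cx[j]; cy <- g$cells$cy[j]
  seg <- data.frame(x1 = cx - 250, y1 = cy, x2 = cx + 250, y2 = cy)
  g1 <- aggregate_streets(g, seg)
  expect_equal(g1$cells$street_length[j], 500, tolerance = 1e-9)
  # segment crossing the vertical shared edge at its midpoint -> 50/50
  ex <- cx + sqrt(3) / 2 * g$s
  seg2 <- data.frame(x1 = ex - 100, y1 = cy, x2 = ex + 100, y2 = cy)
  g2 <- aggregate_streets(g, seg2)
  touched <- which(g2$cells$street_length > 0)
  expect_length(touched, 2)
  expect_equal(g2$cells$street_length[touched], c(100, 100), tolerance = 1e-9)
  # random network conservation
  set.seed(7)
  net <- data.frame(x1 = runif(80, 100, 1900), y1 = runif(80, 100, 1900))
  net$x2 <- pmin(1900, net$x1 + runif(80, -300, 300))
  net$y2 <- pmin(1900, net$y1 + runif(80, -300, 300))
  g3 <- aggregate_streets(g, net)
  expect_rel_equal(sum(g3$cells$street_length),
                   sum(sqrt((net$x2 - net$x1)^2 + (net$y2 - net$y1)^2)), tol = 1e-6)
})

test_that("POI counting conserves totals and assigns edge points once", {
  g <- make_grid(c(0, 0, 2000, 2000))
  cid <- cell_for_points(g, rbind(c(1000, 1000)))
  j <- match(cid, g$cells$cell_id)
  cx <- g$cells$cx[j]; cy <- g$cells$cy[j]
  pois <- data.frame(x = cx + c(-5, 0, 5), y = cy + c(0, 5, -5), category = "retail")
  g1 <- count_pois(g, pois)
  expect_equal(g1$cells$poi_retail[j], 3)
  expect_equal(sum(g1$cells$poi_retail), 3)
  # point exactly on the shared vertical edge: counted once, lower cell_id
  ex <- cx + sqrt(3) / 2 * g$s
  g2 <- count_pois(g, data.frame(x = ex, y = cy, category = "retail"))
  expect_equal(sum(g2$cells$poi_retail), 1)
  winner <- g2$cells$cell_id[g2$cells$poi_retail == 1]
  neighbour <- cell_for_points(g, rbind(c(ex + 1, cy)))
  expect_equal(winner, min(cid, neighbour))
  expect_error(count_pois(g, data.frame(x = 1, y = 1, category = "spaceport")),
               class = "routexpose_config")
  # scattered conservation
  set.seed(9)
  many <- data.frame(x = runif(1000, 0, 2000), y = runif(1000, 0, 2000),
                     category = sample(poi_categories(), 1000, replace = TRUE))
  g3 <- count_pois(g, many)
  expect_equal(sum(as.matrix(g3$cells[grep("^poi_", names(g3$cells))])), 1000)
})

test_that("majority noise class is selected, with ties to the louder class", {
  sc <- noise_scheme("london6")
  g <- make_grid(c(0, 0, 2000, 2000))
  cid <- cell_for_points(g, rbind(c(1000, 1000)))
  j <- match(cid, g$cells$cell_id)
  cx <- g$cells$cx[j]; cy <- g$cells$cy[j]
  ext <- c(cx - 1500, cy - 1500, cx + 1500, cy + 1500)
  rect <- function(x0, y0, x1, y1) rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  # single class covering everything -> that class
  g1 <- assign_noise(g, list(polygons = list(rect(ext[1], ext[2], ext[3], ext[4])),
                             class = 2L), sc)
  expect_true(all(g1$cells$noise_class %in% c(1L, 2L)))  # 1 = outside mapped extent
  expect_equal(g1$cells$noise_class[j], 2L)
  # 50/50 split between classes 1 and 3 down the cell's vertical midline -> 3
  g2 <- assign_noise(g, list(polygons = list(rect(ext[1], ext[2], cx, ext[4]),
                                             rect(cx, ext[2], ext[3], ext[4])),
                             class = c(1L, 3L)), sc)
  expect_equal(g2$cells$noise_class[j], 3L)
  # 70/30 majority -> the 70% class even when quieter
  seventy <- cx - sqrt(3) / 2 * g$s + 0.7 * sqrt(3) * g$s   # crude 70% x-cut
  g3 <- assign_noise(g, list(polygons = list(rect(ext[1], ext[2], seventy, ext[4]),
                                             rect(seventy, ext[2], ext[3], ext[4])),
                             class = c(1L, 2L)), sc)
  expect_equal(g3$cells$noise_class[j], 1L)
  # a hole in the mapped area inside a cell -> coverage error
  expect_error(assign_noise(g, list(polygons = list(rect(ext[1], ext[2], cx - 400, ext[4]),
                                                    rect(cx + 400, ext[2], ext[3], ext[4])),
                                    class = c(1L, 2L)), sc),
               class = "routexpose_coverage")
})

test_that("re-aggregating with empty inputs changes nothing (idempotence)", {
  cfg <- small_city_config(seed = 3)
  city <- generate_city(cfg)
  g <- make_grid(cfg$bbox)
  g <- aggregate_buildings(g, city$buildings)
  g <- aggregate_streets(g, city$streets)
  g <- count_pois(g, city$pois)
  g2 <- aggregate_buildings(g, list())
  g2 <- aggregate_streets(g2, data.frame(x1 = numeric(0), y1 = numeric(0),
                                         x2 = numeric(0), y2 = numeric(0)))
  g2 <- count_pois(g2, data.frame(x = numeric(0), y = numeric(0), category = character(0)))
  expect_identical(g$cells, g2$cells)
})

test_that("grids persist through JSON round trips", {
  cfg <- small_city_config(seed = 3)
  city <- generate_city(cfg)
  g <- make_grid(cfg$bbox)
  g <- aggregate_buildings(g, city$buildings)
  g <- aggregate_streets(g, city$streets)
  g <- count_pois(g, city$pois)
  g <- assign_noise(g, city$noise, city$scheme)
  p <- tempfile(fileext = ".json")
  write_grid(g, p)
  g2 <- read_grid(p)
  expect_equal(g2$cells$building_area, g$cells$building_area)
  expect_equal(g2$cells$noise_class, g$cells$noise_class)
  expect_equal(g2$cells$poi_retail, g$cells$poi_retail)
})
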