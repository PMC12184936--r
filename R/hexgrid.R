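# Equal-area hexagonal tessellation and conservative spatial aggregation.
#
# Cells are pointy-top regular hexagons addressed by axial coordinates
# (q, r); centres are at x = s*sqrt(3)*(q + r/2), y = 1.5*s*r, where s is
# the circumradius (edge length). cell_id runs row-major (ascending r, then
# q), which gives the stable row/column id scheme used for all deterministic
# tie-breaks (shared edges and vertices are always attributed to the lowest
# cell_id).

SQ3 <- sqrt(3)

hex_vertices <- function(cx, cy, s) {
  ang <- pi / 180 * seq(30, 330, by = 60)  # CCW
  cbind(cx + s * cos(ang), cy + s * sin(ang))
}

#' Build an equal-area hexagonal grid covering a bounding box
#'
#' Cells are regular pointy-top hexagons of exactly \code{cell_area} square
#' metres (edge length \eqn{s = \sqrt{2A/(3\sqrt3)}}). The grid includes
#' every cell whose centre lies within one circumradius of the box, which
#' guarantees the box is fully covered.
#'
#' @param bbox numeric \code{c(xmin, ymin, xmax, ymax)} in metres
#' @param cell_area cell area in square metres (default 250000, i.e. 25 ha)
#' @return a \code{hex_grid}: list with edge length \code{s},
#'   \code{cell_area}, \code{bbox}, a \code{cells} data frame
#'   (\code{cell_id, q, r, cx, cy, building_area, street_length,
#'   noise_class}) and the list of cell polygons
#' @examples
#' g <- make_grid(c(0, 0, 2000, 2000))
#' nrow(g$cells)
#' @export
make_grid <- function(bbox, cell_area = 250000) {
  bbox <- check_bbox(bbox)
  if (!is.numeric(cell_area) || length(cell_area) != 1L || !is.finite(cell_area) || cell_area <= 0)
    rx_stop("invalid_config", "cell_area must be a positive number")
  s <- sqrt(2 * cell_area / (3 * SQ3))
  pad <- s * (1 + 1e-9)
  r_rng <- c(ceiling((bbox[2] - pad) / (1.5 * s)), floor((bbox[4] + pad) / (1.5 * s)))
  rows <- list(); n <- 0L
  for (r in seq.int(r_rng[1], r_rng[2])) {
    qlo <- ceiling((bbox[1] - pad) / (SQ3 * s) - r / 2)
    qhi <- floor((bbox[3] + pad) / (SQ3 * s) - r / 2)
    if (qhi < qlo) next
    q <- seq.int(qlo, qhi)
    n <- n + 1L
    rows[[n]] <- data.frame(q = q, r = r)
  }
  cells <- do.call(rbind, rows)
  cells <- cells[order(cells$r, cells$q), , drop = FALSE]
  cells$cell_id <- seq_len(nrow(cells))
  cells$cx <- SQ3 * s * (cells$q + cells$r / 2)
  cells$cy <- 1.5 * s * cells$r
  cells$building_area <- 0
  cells$street_length <- 0
  cells$noise_class <- NA_integer_
  rownames(cells) <- NULL
  polys <- lapply(seq_len(nrow(cells)), function(i) hex_vertices(cells$cx[i], cells$cy[i], s))
  grid <- list(s = s, cell_area = cell_area, bbox = bbox,
               cells = cells[, c("cell_id", "q", "r", "cx", "cy",
                                 "building_area", "street_length", "noise_class")],
               polys = polys,
               key = paste(cells$q, cells$r, sep = ":"))
  class(grid) <- "hex_grid"
  grid
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("hex_grid: %d cells of %.0f m2 (edge %.2f m) covering [%g, %g] x [%g, %g]\n",
              nrow(x$cells), x$cell_area, x$s, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

AX_OFFSETS <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))

# Vectorised axial rounding: fractional axial coords -> nearest hex.
axial_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = rx, r = rz)
}

#' Locate the grid cell containing each point
#'
#' Points on a shared edge or vertex belong to every closed hexagon that
#' touches them; the lowest \code{cell_id} wins, so assignment is
#' deterministic and counts are conserved.
#'
#' @param grid a \code{hex_grid}
#' @param pts n x 2 matrix of coordinates
#' @return integer vector of cell ids (NA outside the grid)
#' @export
cell_for_points <- function(grid, pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) rx_stop("invalid_config", "pts must be an n x 2 matrix")
  s <- grid$s
  qf <- (SQ3 / 3 * pts[, 1] - pts[, 2] / 3) / s
  rf <- (2 / 3) * pts[, 2] / s
  base <- axial_round(qf, rf)
  n <- nrow(pts)
  best <- rep(NA_integer_, n)
  tol <- 1e-9 * s
  # canonical CCW hexagon vertices (unit circumradius), for half-plane tests
  v <- hex_vertices(0, 0, 1)
  for (k in seq_len(nrow(AX_OFFSETS))) {
    qq <- base[, 1] + AX_OFFSETS[k, 1]
    rr <- base[, 2] + AX_OFFSETS[k, 2]
    idx <- match(paste(qq, rr, sep = ":"), grid$key)
    ok <- !is.na(idx)
    if (!any(ok)) next
    cx <- SQ3 * s * (qq + rr / 2)
    cy <- 1.5 * s * rr
    dx <- (pts[, 1] - cx) / s
    dy <- (pts[, 2] - cy) / s
    inside <- ok
    for (e in 1:6) {
      a <- v[e, ]; b <- v[if (e == 6) 1 else e + 1, ]
      cr <- (b[1] - a[1]) * (dy - a[2]) - (b[2] - a[2]) * (dx - a[1])
      inside <- inside & (cr >= -tol)
    }
    cand <- grid$cells$cell_id[idx]
    upd <- inside & (is.na(best) | cand < best)
    best[upd] <- cand[upd]
  }
  best
}

# Row indices of cells whose hexagon could intersect the rectangle bb
# (xmin, ymin, xmax, ymax): centres within one circumradius of bb.
cells_near_bbox <- function(grid, bb) {
  s <- grid$s
  pad <- s * (1 + 1e-9)
  r_rng <- c(ceiling((bb[2] - pad) / (1.5 * s)), floor((bb[4] + pad) / (1.5 * s)))
  if (r_rng[2] < r_rng[1]) return(integer(0))
  out <- integer(0)
  for (r in seq.int(r_rng[1], r_rng[2])) {
    qlo <- ceiling((bb[1] - pad) / (SQ3 * s) - r / 2)
    qhi <- floor((bb[3] + pad) / (SQ3 * s) - r / 2)
    if (qhi < qlo) next
    idx <- match(paste(seq.int(qlo, qhi), r, sep = ":"), grid$key)
    out <- c(out, idx[!is.na(idx)])
  }
  sort(out)
}

#' Aggregate building polygons into per-cell built area
#'
#' Each building is clipped against every cell it overlaps, so a polygon
#' spanning several cells contributes each clipped part to its own cell and
#' total area is conserved.
#'
#' @param grid a \code{hex_grid}
#' @param buildings list of polygon vertex matrices (n x 2, metres), or a
#'   single matrix
#' @return the grid with updated \code{building_area}
#' @export
aggregate_buildings <- function(grid, buildings) {
  if (is.matrix(buildings)) buildings <- list(buildings)
  for (i in seq_along(buildings)) {
    p <- as.matrix(buildings[[i]])
    if (nrow(p) < 3L || !poly_is_simple(p))
      rx_stop("geometry", sprintf("building %d is not a valid simple polygon", i), feature = i)
    area <- poly_area(p)
    if (area <= 0) next
    cells <- cell_for_points(grid, p)
    if (length(unique(cells)) == 1L && !is.na(cells[1]) && is_convex(p)) {
      # convex polygon with all vertices in one convex cell lies inside it
      j <- match(cells[1], grid$cells$cell_id)
      grid$cells$building_area[j] <- grid$cells$building_area[j] + area
      next
    }
    bb <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
    for (j in cells_near_bbox(grid, bb)) {
      cp <- clip_poly_convex(p, grid$polys[[j]])
      if (!is.null(cp)) grid$cells$building_area[j] <- grid$cells$building_area[j] + poly_area(cp)
    }
  }
  grid
}

is_convex <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(TRUE)
  a <- p[c(2:n, 1L), ] - p
  cr <- a[, 1] * a[c(2:n, 1L), 2] - a[, 2] * a[c(2:n, 1L), 1]
  all(cr >= -1e-12) || all(cr <= 1e-12)
}

# Assign the [t0,t1] span of one segment across candidate cells, resolving
# any shared-edge overlap toward the lowest cell_id. Returns a data frame
# (cell row index, length assigned).
assign_segment <- function(grid, p, q) {
  L <- seg_len(p, q)
  if (L < 1e-12) return(NULL)
  ends <- cell_for_points(grid, rbind(p, q))
  if (!anyNA(ends) && ends[1] == ends[2]) {
    return(data.frame(j = match(ends[1], grid$cells$cell_id), len = L))
  }
  bb <- c(min(p[1], q[1]), min(p[2], q[2]), max(p[1], q[1]), max(p[2], q[2]))
  cand <- cells_near_bbox(grid, bb)
  if (!length(cand)) return(NULL)
  res_j <- integer(0); res_len <- numeric(0)
  covered <- matrix(numeric(0), ncol = 2)  # disjoint ascending [t0,t1] rows
  for (j in cand) {  # ascending row index == ascending cell_id
    tv <- clip_seg_convex(p, q, grid$polys[[j]])
    if (is.null(tv)) next
    # subtract already-covered parts
    t0 <- tv[1]; t1 <- tv[2]
    segs <- rbind(c(t0, t1))
    if (nrow(covered)) {
      for (ci in seq_len(nrow(covered))) {
        new <- matrix(numeric(0), ncol = 2)
        for (si in seq_len(nrow(segs))) {
          a <- segs[si, 1]; b <- segs[si, 2]
          lo <- covered[ci, 1]; hi <- covered[ci, 2]
          if (hi <= a || lo >= b) { new <- rbind(new, c(a, b)); next }
          if (lo > a) new <- rbind(new, c(a, lo))
          if (hi < b) new <- rbind(new, c(hi, b))
        }
        segs <- new
        if (!nrow(segs)) break
      }
    }
    got <- if (nrow(segs)) sum(pmax(0, segs[, 2] - segs[, 1])) else 0
    if (got > 1e-12) {
      res_j <- c(res_j, j); res_len <- c(res_len, got * L)
      covered <- rbind(covered, c(t0, t1))
      covered <- merge_intervals(covered)
    }
  }
  if (!length(res_j)) return(NULL)
  data.frame(j = res_j, len = res_len)
}

merge_intervals <- function(m) {
  if (nrow(m) < 2L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2] + 1e-12) out[k, 2] <- max(out[k, 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

#' Aggregate street polylines into per-cell street length
#'
#' @param grid a \code{hex_grid}
#' @param streets data frame of segments with columns \code{x1, y1, x2, y2}
#'   (one row per straight segment), or a list of polyline coordinate
#'   matrices
#' @return the grid with updated \code{street_length}
#' @export
aggregate_streets <- function(grid, streets) {
  segs <- as_segments(streets)
  for (i in seq_len(nrow(segs))) {
    a <- assign_segment(grid, c(segs$x1[i], segs$y1[i]), c(segs$x2[i], segs$y2[i]))
    if (!is.null(a)) {
      grid$cells$street_length[a$j] <- grid$cells$street_length[a$j] + a$len
    }
  }
  grid
}

as_segments <- function(streets) {
  if (is.data.frame(streets)) {
    need <- c("x1", "y1", "x2", "y2")
    if (!all(need %in% names(streets)))
      rx_stop("invalid_config", "street data frame needs columns x1, y1, x2, y2")
    return(streets)
  }
  if (is.matrix(streets)) streets <- list(streets)
  rows <- lapply(streets, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2L) rx_stop("geometry", "polyline needs at least 2 points")
    data.frame(x1 = m[-nrow(m), 1], y1 = m[-nrow(m), 2], x2 = m[-1, 1], y2 = m[-1, 2])
  })
  do.call(rbind, rows)
}

#' Default point-of-interest categories
#'
#' The six functional categories used to regroup points of interest:
#' educational, recreational, medical, public services, retail, others.
#' @return character vector of length 6
#' @export
poi_categories <- function() {
  c("educational", "recreational", "medical", "public services", "retail", "others")
}

poi_col <- function(category) paste0("mean_poi_", gsub("[^a-z0-9]+", "_", tolower(category)))
poi_count_col <- function(category) paste0("poi_", gsub("[^a-z0-9]+", "_", tolower(category)))

#' Count categorised points of interest per cell
#'
#' A point on a shared cell edge is counted once, in the lowest
#' \code{cell_id}, so totals are conserved.
#'
#' @param grid a \code{hex_grid}
#' @param pois data frame with columns \code{x, y, category}
#' @param categories allowed category labels (defines the count columns)
#' @return the grid with per-category count columns \code{poi_<category>}
#' @export
count_pois <- function(grid, pois, categories = poi_categories()) {
  cols <- vapply(categories, poi_count_col, "")
  for (cl in cols) if (is.null(grid$cells[[cl]])) grid$cells[[cl]] <- 0
  if (nrow(pois) == 0L) return(grid)
  bad <- setdiff(unique(pois$category), categories)
  if (length(bad))
    rx_stop("config", sprintf("unknown POI category: %s", paste(bad, collapse = ", ")))
  ids <- cell_for_points(grid, cbind(pois$x, pois$y))
  keep <- !is.na(ids)
  if (any(keep)) {
    tab <- table(factor(match(ids[keep], grid$cells$cell_id), levels = seq_len(nrow(grid$cells))),
                 factor(pois$category[keep], levels = categories))
    for (ci in seq_along(categories)) {
      grid$cells[[cols[ci]]] <- grid$cells[[cols[ci]]] + as.numeric(tab[, ci])
    }
  }
  grid
}

#' Assign each cell the majority noise class
#'
#' Each cell takes the ordinal class whose polygons cover the largest area
#' within it; exact ties go to the louder class (conservative exposure).
#' Cells whose overlap with the mapped extent is more than 1\% uncovered
#' raise a coverage error; cells wholly outside the mapped extent take the
#' quietest class.
#'
#' @param grid a \code{hex_grid}
#' @param noise list with \code{polygons} (list of vertex matrices) and
#'   \code{class} (integer class index per polygon, 1 = quietest)
#' @param scheme the \code{noise_scheme} the classes index into
#' @return the grid with \code{noise_class} filled in
#' @export
assign_noise <- function(grid, noise, scheme) {
  K <- n_classes(scheme)
  if (any(noise$class < 1L | noise$class > K))
    rx_stop("config", "noise class index outside the scheme")
  nc <- nrow(grid$cells)
  A <- matrix(0, nc, K)
  ext <- c(Inf, Inf, -Inf, -Inf)
  for (i in seq_along(noise$polygons)) {
    p <- as.matrix(noise$polygons[[i]])
    ext <- c(pmin(ext[1:2], c(min(p[, 1]), min(p[, 2]))),
             pmax(ext[3:4], c(max(p[, 1]), max(p[, 2]))))
    k <- noise$class[i]
    cells <- cell_for_points(grid, p)
    if (length(unique(cells)) == 1L && !is.na(cells[1]) && is_convex(p)) {
      j <- match(cells[1], grid$cells$cell_id)
      A[j, k] <- A[j, k] + poly_area(p)
      next
    }
    bb <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
    for (j in cells_near_bbox(grid, bb)) {
      cp <- clip_poly_convex(p, grid$polys[[j]])
      if (!is.null(cp)) A[j, k] <- A[j, k] + poly_area(cp)
    }
  }
  # coverage is judged against each cell's overlap with the mapped extent
  rect <- rbind(c(ext[1], ext[2]), c(ext[3], ext[2]), c(ext[3], ext[4]), c(ext[1], ext[4]))
  tie_tol <- 1e-7 * grid$cell_area
  for (j in seq_len(nc)) {
    cp <- clip_poly_convex(grid$polys[[j]], rect)
    target <- if (is.null(cp)) 0 else poly_area(cp)
    covered <- sum(A[j, ])
    if (target > 1e-9 && covered < 0.99 * target)
      rx_stop("coverage",
              sprintf("cell %d: %.1f%% of its mapped area lacks noise coverage",
                      grid$cells$cell_id[j], 100 * (1 - covered / target)),
              cell_id = grid$cells$cell_id[j])
    if (covered <= 1e-9) {
      grid$cells$noise_class[j] <- 1L
    } else {
      grid$cells$noise_class[j] <- max(which(A[j, ] >= max(A[j, ]) - tie_tol))
    }
  }
  grid$scheme_name <- scheme$name
  grid
}
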