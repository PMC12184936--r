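# Planar geometry primitives on matrices of (x, y) rows. All coordinates are
# metres in a projected plane. Hexagon cells are convex, so polygon-polygon
# intersection only ever needs clipping against a convex clipper
# (Sutherland-Hodgman) and segment-polygon intersection reduces to
# parametric half-plane clipping (Cyrus-Beck).

# Signed area (positive for counter-clockwise rings).
poly_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

poly_area <- function(xy) abs(poly_area_signed(xy))

ensure_ccw <- function(xy) if (poly_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy

# Sutherland-Hodgman: clip an arbitrary simple polygon `subject` against a
# convex CCW polygon `clip`. Returns a vertex matrix (possibly with repeated
# vertices, harmless for area) or NULL when the intersection is empty.
clip_poly_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # side > 0 means strictly inside (left of a->b for a CCW clipper)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(2:n, 1L)[seq_len(n)]
    keep <- vector("list", 2L * n)
    m <- 0L
    for (j in seq_len(n)) {
      k <- nxt[j]
      sj <- side[j]; sk <- side[k]
      if (sj >= 0) { m <- m + 1L; keep[[m]] <- out[j, ] }
      if ((sj > 0 && sk < 0) || (sj < 0 && sk > 0)) {
        t <- sj / (sj - sk)
        m <- m + 1L
        keep[[m]] <- out[j, ] + t * (out[k, ] - out[j, ])
      }
    }
    if (m == 0L) return(NULL)
    out <- do.call(rbind, keep[seq_len(m)])
  }
  if (is.null(out) || nrow(out) < 3L) return(NULL)
  out
}

# Cyrus-Beck: intersection of segment p->q with a convex CCW polygon.
# Returns c(t0, t1) in [0, 1] (parameter range inside) or NULL.
clip_seg_convex <- function(p, q, clip) {
  t0 <- 0; t1 <- 1
  nc <- nrow(clip)
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  for (i in seq_len(nc)) {
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # f(t) = cross(b-a, p + t d - a) >= 0 keeps the inside half-plane
    c0 <- ex * (p[2] - a[2]) - ey * (p[1] - a[1])
    c1 <- ex * dy - ey * dx
    if (abs(c1) < 1e-12) {
      if (c0 < -1e-9) return(NULL)
    } else if (c1 > 0) {
      t0 <- max(t0, -c0 / c1)
    } else {
      t1 <- min(t1, -c0 / c1)
    }
    if (t0 >= t1 - 1e-12) {
      if (t0 > t1) return(NULL)
    }
  }
  if (t1 - t0 <= 0) return(NULL)
  c(t0, t1)
}

point_in_poly_convex <- function(pt, clip, tol = 1e-9) {
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    if ((b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1]) < -tol) return(FALSE)
  }
  TRUE
}

seg_len <- function(p, q) sqrt(sum((q - p)^2))

# Distances from a set of points (n x 2) to the nearest of a set of segments
# (m x 4 as x1,y1,x2,y2). Vectorised over points per segment.
dist_points_segments <- function(pts, segs) {
  if (is.null(segs) || nrow(segs) == 0L) return(rep(Inf, nrow(pts)))
  best <- rep(Inf, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 < 1e-18) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Simple-polygon validity: no two non-adjacent edges properly intersect.
poly_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  seg <- cbind(xy, xy[c(2:n, 1L), , drop = FALSE])
  inter <- function(i, j) {
    p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]; p3 <- seg[j, 1:2]; p4 <- seg[j, 3:4]
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    for (j in js) if (inter(i, j)) return(FALSE)
  }
  TRUE
}
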