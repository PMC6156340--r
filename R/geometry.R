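# Internal planar geometry helpers. Polygons are two-column matrices
# (x, y), vertices in counter-clockwise order, not closed (first vertex
# not repeated). All zone polygons in this package are convex: Voronoi
# cells are convex and are only ever clipped against the convex tissue
# polygon, so convex-only algorithms suffice throughout.

# Signed area via the shoelace formula; positive for CCW orientation.
.poly_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

.poly_area <- function(poly) abs(.poly_signed_area(poly))

# CCW convex hull of a point set; errors if degenerate (< 3 points or
# all collinear).
.convex_hull <- function(x, y) {
  if (length(x) < 3L)
    stop("convex hull needs at least 3 points", call. = FALSE)
  idx <- grDevices::chull(x, y)
  if (length(idx) < 3L)
    stop("points are collinear; tissue polygon is degenerate", call. = FALSE)
  poly <- cbind(x = x[idx], y = y[idx])
  # chull returns clockwise order; flip to CCW
  if (.poly_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

# Sutherland-Hodgman clip of a convex polygon against the half-plane
# a*x + b*y <= c. Returns a polygon matrix, possibly with 0 rows.
.clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1L] + b * poly[, 2L] - cc
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0L, , drop = FALSE])
  xs <- numeric(2L * n); ys <- numeric(2L * n); k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L; xs[k] <- poly[i, 1L]; ys[k] <- poly[i, 2L]
    }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      xs[k] <- poly[i, 1L] + t * (poly[j, 1L] - poly[i, 1L])
      ys[k] <- poly[i, 2L] + t * (poly[j, 2L] - poly[i, 2L])
    }
  }
  cbind(x = xs[seq_len(k)], y = ys[seq_len(k)])
}

# Distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorised
# over points.
.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance between the boundaries of two convex polygons. Zone
# polygons are interior-disjoint by construction, so boundary distance 0
# means the polygons touch (shared edge or point).
.poly_min_dist <- function(p1, p2) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  best <- Inf
  for (i in seq_len(n2)) {
    j <- if (i == n2) 1L else i + 1L
    best <- min(best, min(.dist_point_segment(p1[, 1L], p1[, 2L],
                                              p2[i, 1L], p2[i, 2L],
                                              p2[j, 1L], p2[j, 2L])))
    if (best == 0) return(0)
  }
  for (i in seq_len(n1)) {
    j <- if (i == n1) 1L else i + 1L
    best <- min(best, min(.dist_point_segment(p2[, 1L], p2[, 2L],
                                              p1[i, 1L], p1[i, 2L],
                                              p1[j, 1L], p1[j, 2L])))
    if (best == 0) return(0)
  }
  best
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards. seed = NULL leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
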