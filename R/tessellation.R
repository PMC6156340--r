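#' Tissue area and clipping polygon
#'
#' Estimates the tissue footprint of a slide from its cell positions.
#' The convex hull of all cell centroids is used both as the area entering
#' the seed-count rule (see [seed_count()]) and as the polygon to which
#' unbounded Voronoi cells are clipped.
#'
#' @param table a [cell_table()].
#' @param method hull construction. Only `"convex_hull"` is implemented;
#'   `"alpha_shape"` is reserved and currently errors.
#' @return list with `area` (um^2) and `polygon` (CCW two-column matrix).
#' @export
tissue_area <- function(table, method = c("convex_hull", "alpha_shape")) {
  method <- match.arg(method)
  if (method == "alpha_shape")
    stop("alpha_shape tissue outlines are not implemented in this build; ",
         "use method = \"convex_hull\"", call. = FALSE)
  poly <- .convex_hull(table$x, table$y)
  list(area = .poly_area(poly), polygon = poly)
}

#' Number of Voronoi seeds for a tissue area
#'
#' The number of zones scales sub-linearly with tissue area:
#' `N = floor(sqrt(area / area_unit_scale) / 3)`, with a floor of one
#' seed. Scaling with area rather than with cancer-cell count keeps the
#' spatial resolution of the tessellation comparable across tumors with
#' very different cellularity (a fibrotic tumor still gets enough zones
#' for local statistics). `area_unit_scale` converts um^2 into the unit
#' in which the square-root rule is applied; the appropriate value for a
#' given cohort is a calibration choice (the rule's units are not
#' dimensionless), so it is exposed rather than hidden.
#'
#' @param area tissue area in um^2 (positive).
#' @param area_unit_scale um^2 per area unit; default 1.
#' @return integer seed count, at least 1.
#' @examples
#' seed_count(36)         # sqrt(36)/3 = 2
#' seed_count(2250000)    # 1500/3 = 500
#' @export
seed_count <- function(area, area_unit_scale = 1) {
  if (!is.finite(area) || area <= 0)
    stop("area must be positive", call. = FALSE)
  if (!is.finite(area_unit_scale) || area_unit_scale <= 0)
    stop("area_unit_scale must be positive", call. = FALSE)
  max(1L, as.integer(floor(sqrt(area / area_unit_scale) / 3)))
}

#' Randomly select seed cells
#'
#' Seeds are drawn uniformly without replacement from the cells of the
#' target class (cancer cells by default), so cancer-dense regions
#' receive proportionally more seeds and every zone contains at least
#' its seed cell.
#'
#' @param table a [cell_table()].
#' @param n number of seeds.
#' @param target_class class from which seeds are drawn.
#' @param rng_seed optional integer; when given, selection is
#'   reproducible and the caller's RNG state is left untouched.
#' @return character vector of `n` distinct cell ids.
#' @export
select_seeds <- function(table, n, target_class = "cancer", rng_seed = NULL) {
  pool <- which(table$cell_class == target_class)
  if (n > length(pool))
    stop("requested ", n, " seeds but only ", length(pool), " ",
         target_class, " cells available", call. = FALSE)
  if (n < 1L) stop("need at least one seed", call. = FALSE)
  idx <- .with_seed(rng_seed, pool[sample.int(length(pool), n)])
  as.character(table$cell_id[idx])
}

#' Build a Voronoi zone map
#'
#' Partitions the slide into zones: each seed's zone is the set of cells
#' closer (Euclidean) to that seed than to any other seed, and its
#' polygon is the seed's Voronoi cell clipped to the tissue polygon.
#' Cells exactly equidistant from two seeds are assigned to the seed
#' with the smaller cell id, a deterministic tie-break independent of
#' seed order. Seeds with duplicated coordinates are rejected.
#'
#' @param table a [cell_table()].
#' @param seeds character vector of seed cell ids (present in `table`,
#'   distinct coordinates).
#' @param tissue_polygon convex CCW polygon to clip against; defaults to
#'   the convex hull of the table.
#' @return object of class `zone_map`: list with `seeds` (data frame of
#'   `zone_id`, `cell_id`, `x`, `y`), `polygons` (list of two-column
#'   matrices), `assignment` (data frame `cell_id`, `zone_id`), `m`
#'   (number of zones) and `tissue_polygon`.
#' @export
build_zone_map <- function(table, seeds, tissue_polygon = NULL) {
  stopifnot(is_cell_table(table))
  if (length(seeds) == 0L) stop("empty seed list", call. = FALSE)
  pos <- match(as.character(seeds), as.character(table$cell_id))
  if (anyNA(pos))
    stop("seed id(s) not present in table: ",
         paste(seeds[is.na(pos)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(pos)) stop("duplicate seed ids", call. = FALSE)
  sx <- table$x[pos]; sy <- table$y[pos]
  if (anyDuplicated(cbind(sx, sy)))
    stop("two seeds share identical coordinates; duplicate seed ",
         "coordinates are rejected for reproducibility", call. = FALSE)
  if (is.null(tissue_polygon)) tissue_polygon <- tissue_area(table)$polygon
  m <- length(seeds)
  polygons <- .voronoi_polygons(sx, sy, tissue_polygon)
  zone_id <- sprintf("z%03d", seq_len(m))
  assignment <- data.frame(
    cell_id = as.character(table$cell_id),
    zone_id = zone_id[.assign_nearest(table$x, table$y, sx, sy,
                                      table$cell_id[pos])],
    stringsAsFactors = FALSE)
  structure(list(
    seeds = data.frame(zone_id = zone_id, cell_id = as.character(seeds),
                       x = sx, y = sy, stringsAsFactors = FALSE),
    polygons = stats::setNames(polygons, zone_id),
    assignment = assignment,
    m = m,
    tissue_polygon = tissue_polygon,
    slide_id = slide_id(table)
  ), class = "zone_map")
}

# Nearest-seed index for each cell, ties to the seed with the smaller
# cell_id. Chunked so the cells x seeds distance matrix stays small.
.assign_nearest <- function(x, y, sx, sy, seed_ids) {
  n <- length(x); m <- length(sx)
  # rank seeds by id so ties resolve to the smallest id
  id_rank <- rank(seed_ids, ties.method = "first")
  out <- integer(n)
  chunk <- max(1L, as.integer(2e6 / m))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(x[idx], sx, "-")^2 + outer(y[idx], sy, "-")^2
    out[idx] <- apply(d2, 1L, function(row) {
      cand <- which(row <= min(row) * (1 + 1e-12))
      cand[which.min(id_rank[cand])]
    })
  }
  out
}

# Voronoi cells by incremental half-plane clipping. For seed i, start
# from the tissue polygon and clip by the perpendicular bisector against
# other seeds in order of increasing distance; once the next seed is
# farther than twice the seed's distance to its farthest remaining
# vertex, no later bisector can cut and we stop.
.voronoi_polygons <- function(sx, sy, tissue_polygon) {
  m <- length(sx)
  polys <- vector("list", m)
  for (i in seq_len(m)) {
    poly <- tissue_polygon
    if (m > 1L) {
      d2 <- (sx - sx[i])^2 + (sy - sy[i])^2
      ord <- order(d2)
      ord <- ord[ord != i]
      rmax2 <- max((poly[, 1L] - sx[i])^2 + (poly[, 2L] - sy[i])^2)
      for (j in ord) {
        if (d2[j] > 4 * rmax2) break
        a <- sx[j] - sx[i]; b <- sy[j] - sy[i]
        cc <- (sx[j]^2 - sx[i]^2 + sy[j]^2 - sy[i]^2) / 2
        poly <- .clip_halfplane(poly, a, b, cc)
        if (nrow(poly) < 3L) break
        rmax2 <- max((poly[, 1L] - sx[i])^2 + (poly[, 2L] - sy[i])^2)
      }
    }
    polys[[i]] <- poly
  }
  polys
}

#' Queen-contiguity weights between zones
#'
#' Two zones are neighbors when their polygons share a common edge or a
#' single point (queen contiguity). Zone polygons arising from one
#' tessellation are interior-disjoint, so contact is detected as a
#' boundary-to-boundary distance not exceeding `tol`.
#'
#' @param zone_map a [build_zone_map()] result.
#' @param tol contact tolerance in um. The default (1e-6 um) is far
#'   below any biological length scale while staying clear of double
#'   rounding in vertex coordinates at slide scale.
#' @return object of class `zone_weights`: list with `zone_ids`, binary
#'   symmetric matrix `w` (zero diagonal) and `degree` (row sums).
#' @export
neighbor_graph <- function(zone_map, tol = 1e-6) {
  polys <- zone_map$polygons
  m <- length(polys)
  areas <- vapply(polys, .poly_area, numeric(1))
  if (any(areas <= 0))
    stop("degenerate zero-area zone polygon(s): ",
         paste(names(polys)[areas <= 0], collapse = ", "), call. = FALSE)
  bb <- t(vapply(polys, function(p)
    c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L])), numeric(4)))
  w <- matrix(0L, m, m, dimnames = list(names(polys), names(polys)))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      # bounding-box prefilter
      cand <- which(bb[(i + 1L):m, 1L] <= bb[i, 2L] + tol &
                    bb[(i + 1L):m, 2L] >= bb[i, 1L] - tol &
                    bb[(i + 1L):m, 3L] <= bb[i, 4L] + tol &
                    bb[(i + 1L):m, 4L] >= bb[i, 3L] - tol) + i
      for (j in cand) {
        if (.poly_min_dist(polys[[i]], polys[[j]]) <= tol) {
          w[i, j] <- 1L; w[j, i] <- 1L
        }
      }
    }
  }
  structure(list(zone_ids = names(polys), w = w, degree = rowSums(w)),
            class = "zone_weights")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("Voronoi zone map of slide '", x$slide_id, "': ", x$m, " zones, ",
      nrow(x$assignment), " cells assigned\n", sep = "")
  invisible(x)
}

#' @export
print.zone_weights <- function(x, ...) {
  cat("Queen-contiguity weights: ", length(x$zone_ids), " zones, ",
      sum(x$w) / 2, " edges, mean degree ",
      round(mean(x$degree), 2), "\n", sep = "")
  invisible(x)
}

#' Serialise a zone map to GeoJSON
#'
#' Writes one Feature per zone (Polygon geometry in slide coordinates)
#' with `zone_id`, seed `cell_id` and per-class cell counts as
#' properties.
#'
#' @param zone_map a [build_zone_map()] result.
#' @param table the [cell_table()] the map was built on (for counts).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
zones_to_geojson <- function(zone_map, table, path) {
  comp <- zone_composition(zone_map, table)
  features <- lapply(seq_len(zone_map$m), function(i) {
    poly <- zone_map$polygons[[i]]
    ring <- rbind(poly, poly[1L, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(k)
                        c(ring[k, 1L], ring[k, 2L])))),
      properties = list(
        zone_id = zone_map$seeds$zone_id[i],
        seed_cell_id = zone_map$seeds$cell_id[i],
        n_cancer = comp$n_cancer[i],
        n_lymphocyte = comp$n_lymphocyte[i],
        n_stromal = comp$n_stromal[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
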