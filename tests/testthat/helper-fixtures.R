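# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

# Minimal cancer-only cell table on given coordinates.
make_cells <- function(x, y, class = "cancer", area = 40, perimeter = 25,
                       ids = NULL, slide = "fixture") {
  n <- length(x)
  cell_table(data.frame(
    cell_id = ids %||% sprintf("c%03d", seq_len(n)),
    x = x, y = y,
    cell_class = rep_len(class, n),
    nucleus_area = rep_len(area, n),
    nucleus_perimeter = rep_len(perimeter, n),
    stringsAsFactors = FALSE), slide_id = slide)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built zone map from a list of polygons (two-column CCW matrices),
# bypassing the tessellator, for geometry-level tests.
manual_zone_map <- function(polygons, slide = "manual") {
  m <- length(polygons)
  ids <- sprintf("z%03d", seq_len(m))
  structure(list(
    seeds = data.frame(zone_id = ids, cell_id = ids,
                       x = vapply(polygons, function(p) mean(p[, 1]), 0),
                       y = vapply(polygons, function(p) mean(p[, 2]), 0),
                       stringsAsFactors = FALSE),
    polygons = stats::setNames(polygons, ids),
    assignment = data.frame(cell_id = character(0), zone_id = character(0)),
    m = m, tissue_polygon = NULL, slide_id = slide), class = "zone_map")
}

unit_square <- function(x0, y0) {
  cbind(x = x0 + c(0, 1, 1, 0), y = y0 + c(0, 0, 1, 1))
}

# zone_weights from an explicit binary matrix.
weights_from_matrix <- function(w, ids = NULL) {
  ids <- ids %||% sprintf("z%03d", seq_len(nrow(w)))
  dimnames(w) <- list(ids, ids)
  structure(list(zone_ids = ids, w = w, degree = rowSums(w)),
            class = "zone_weights")
}

# Small clustered synthetic slide used by several suites.
small_slide <- function(seed, planted = NULL, n_lymphocyte = 450, ...) {
  cfg <- slide_config(width = 1500, height = 1500, n_cancer = 2500,
                      n_lymphocyte = n_lymphocyte, n_stromal = 500,
                      planted_zones = planted, rng_seed = seed, ...)
  simulate_slide(cfg)
}
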