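#' Detect morphological diversification zones on a slide
#'
#' The full pipeline: tissue polygon and area from the cell positions,
#' seed count from the area rule, random cancer-cell seeds, Voronoi
#' zone map clipped to the tissue polygon, queen-contiguity weights,
#' per-zone shape-factor variability Y, local Moran's I with analytic
#' (and optionally Monte-Carlo) significance, FDR adjustment across the
#' slide's zones, diversification calls, and the sample-level
#' present/absent summary. A single `seed` governs both seed selection
#' and any permutations, so identical inputs and seed give identical
#' output.
#'
#' Zones with fewer than `params$min_cancer_cells_per_zone` cells of the
#' target class are excluded before the spatial test: they are removed
#' from the weights graph (their neighbors do not become adjacent
#' through them) and carry NA statistics in the results.
#'
#' @param table a [cell_table()].
#' @param params a [div_params()].
#' @param area_unit_scale um^2 per area unit in the seed-count rule
#'   (see [seed_count()]).
#' @param tissue_method passed to [tissue_area()].
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `morphozone`: a list with components
#'   `slide_id`, `zone_map`, `weights`, `results` (one row per zone:
#'   `zone_id`, `n_target`, `Y`, `I`, `E_I`, `Var_I`, `z`,
#'   `p_analytic`, `p_permutation`, `q`, `diversified`, `excluded`,
#'   `reason`), `Y_mean`, `params`, `tissue_area` and `summary`
#'   (a one-row data frame, see [summarize_sample()]).
#' @examples
#' cfg <- slide_config(width = 1200, height = 1200, n_cancer = 800,
#'                     n_lymphocyte = 150, n_stromal = 150,
#'                     planted_zones = NULL, rng_seed = 1)
#' sim <- simulate_slide(cfg)
#' fit <- detect_zones(sim$cells, area_unit_scale = 200, seed = 1)
#' summary(fit)
#' @export
detect_zones <- function(table, params = div_params(), area_unit_scale = 1,
                         tissue_method = "convex_hull", seed = NULL) {
  stopifnot(is_cell_table(table), inherits(params, "div_params"))
  .with_seed(seed, {
    tiss <- tissue_area(table, method = tissue_method)
    n_seeds <- seed_count(tiss$area, area_unit_scale)
    seeds <- select_seeds(table, n_seeds, target_class = params$target_class)
    zm <- build_zone_map(table, seeds, tiss$polygon)
    W <- neighbor_graph(zm)
    zv <- zone_variability(zm, table,
                           min_cells = params$min_cancer_cells_per_zone,
                           target_class = params$target_class)
    res <- .zone_test(zv, W, params)
    res <- flag_diversified(res, params, attr(res, "Y_mean"))
    res$diversified[res$excluded] <- FALSE
    structure(list(
      slide_id = slide_id(table),
      zone_map = zm,
      weights = W,
      results = res,
      Y_mean = attr(res, "Y_mean"),
      params = params,
      tissue_area = tiss$area,
      summary = summarize_sample(res, slide_id(table))
    ), class = "morphozone")
  })
}

# Run the spatial test on non-excluded zones and merge back into the
# full zone table. Restricting the weights matrix to the tested zones
# implements the drop-not-bridge rule for excluded zones.
.zone_test <- function(zv, W, params) {
  res <- data.frame(zone_id = zv$zone_id, n_target = zv$n_target, Y = zv$Y,
                    I = NA_real_, E_I = NA_real_, Var_I = NA_real_,
                    z = NA_real_, p_analytic = NA_real_,
                    p_permutation = NA_real_, q = NA_real_,
                    excluded = zv$excluded, reason = zv$reason,
                    stringsAsFactors = FALSE)
  keep <- which(!zv$excluded)
  Y <- zv$Y[keep]
  attr(res, "Y_mean") <- mean(Y)
  if (length(keep) < 4L) {
    res$excluded[keep] <- TRUE
    res$reason[keep] <- "fewer than 4 testable zones on slide"
    return(res)
  }
  Wk <- .subset_weights(W, keep)
  if (params$mean_mode == "global") {
    am <- analytic_moments(Y, Wk, tail = params$tail)
    res$I[keep] <- am$I
    res$E_I[keep] <- am$E_I
    res$Var_I[keep] <- am$Var_I
    res$z[keep] <- am$z
    res$p_analytic[keep] <- am$p_analytic
  } else {
    li <- local_morans_i(Y, Wk, mean_mode = "neighborhood")
    res$I[keep] <- li$I
    attr(res, "Y_mean") <- mean(Y)
  }
  if (params$p_source == "permutation" || params$mean_mode == "neighborhood") {
    res$p_permutation[keep] <- permutation_null(
      Y, Wk, n_permutations = params$n_permutations, tail = params$tail)
  }
  p_use <- if (params$p_source == "analytic" && params$mean_mode == "global")
    res$p_analytic else res$p_permutation
  undef <- keep[is.na(p_use[keep])]
  if (length(undef)) {
    res$excluded[undef] <- TRUE
    res$reason[undef] <- ifelse(res$Var_I[undef] %in% 0,
                                "degenerate null (zero variance or isolated)",
                                "undefined test statistic")
  }
  test_idx <- which(!res$excluded)
  res$q[test_idx] <- fdr_adjust(p_use[test_idx])
  res
}

.subset_weights <- function(W, idx) {
  w <- W$w[idx, idx, drop = FALSE]
  structure(list(zone_ids = W$zone_ids[idx], w = w, degree = rowSums(w)),
            class = "zone_weights")
}

#' @export
print.morphozone <- function(x, ...) {
  s <- x$summary
  cat("Morphological diversification analysis of slide '", x$slide_id,
      "'\n", sep = "")
  cat("  tissue area: ", format(x$tissue_area, big.mark = ","),
      " um^2; zones: ", x$zone_map$m,
      " (", sum(x$results$excluded), " excluded)\n", sep = "")
  cat("  diversified zones: ", s$n_diversified, "/", s$m_zones,
      " (", sprintf("%.1f%%", 100 * s$fraction_diversified), ")",
      "  ->  diversification ",
      if (s$present) "PRESENT" else "ABSENT", "\n", sep = "")
  invisible(x)
}

#' @export
summary.morphozone <- function(object, ...) {
  res <- object$results
  tested <- res[!res$excluded, ]
  out <- list(
    slide = object$summary,
    Y_mean = object$Y_mean,
    Y_range = range(tested$Y),
    params = object$params,
    top = utils::head(tested[order(tested$q), ], 5L))
  class(out) <- "summary.morphozone"
  out
}

#' @export
print.summary.morphozone <- function(x, ...) {
  s <- x$slide
  cat("Slide '", s$slide_id, "': ", s$m_zones, " tested zones, ",
      s$n_diversified, " diversified (",
      sprintf("%.1f%%", 100 * s$fraction_diversified), "); present = ",
      s$present, "\n", sep = "")
  cat("Mean zonal shape variability: ", signif(x$Y_mean, 4),
      " (range ", signif(x$Y_range[1], 4), " - ",
      signif(x$Y_range[2], 4), ")\n", sep = "")
  cat("Test: local Moran's I, ", x$params$tail, ", p from ",
      x$params$p_source, ", BH FDR at alpha = ", x$params$alpha,
      "\n\nMost significant zones:\n", sep = "")
  print(x$top[, c("zone_id", "n_target", "Y", "I", "z", "q", "diversified")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.morphozone <- function(x, ...) x$results

#' Plot a diversification map
#'
#' Draws the zone polygons filled by zonal shape variability Y
#' (light-to-dark) with diversified zones outlined.
#'
#' @param x a [detect_zones()] result.
#' @param highlight color of the diversified-zone outline.
#' @param ... passed to [graphics::plot()].
#' @export
plot.morphozone <- function(x, highlight = "green3", ...) {
  zm <- x$zone_map
  res <- x$results
  Y <- res$Y
  rng <- range(Y, na.rm = TRUE)
  fill <- rep("grey90", length(Y))
  ok <- !is.na(Y)
  if (diff(rng) > 0) {
    ramp <- grDevices::colorRamp(c("#FFF7EC", "#7F0000"))
    fill[ok] <- grDevices::rgb(ramp((Y[ok] - rng[1]) / diff(rng)),
                               maxColorValue = 255)
  }
  tp <- zm$tissue_polygon
  graphics::plot(NA, xlim = range(tp[, 1]), ylim = rev(range(tp[, 2])),
                 asp = 1, xlab = "x (um)", ylab = "y (um)",
                 main = paste0("Slide '", x$slide_id, "'"), ...)
  for (i in seq_len(zm$m))
    graphics::polygon(zm$polygons[[i]], col = fill[i], border = "grey60",
                      lwd = 0.4)
  div <- which(res$diversified)
  for (i in div)
    graphics::polygon(zm$polygons[[i]], col = NA, border = highlight,
                      lwd = 2)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `zones.geojson` (zone polygons with properties),
#' `zone_results.csv` (one row per zone) and `summary.json`.
#'
#' @param fit a [detect_zones()] result.
#' @param table the [cell_table()] used for the fit.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_zone_results <- function(fit, table, dir) {
  stopifnot(inherits(fit, "morphozone"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  zones_to_geojson(fit$zone_map, table, file.path(dir, "zones.geojson"))
  utils::write.csv(fit$results, file.path(dir, "zone_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(fit$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
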