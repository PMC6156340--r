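#' Synthetic slide configuration
#'
#' Describes a synthetic whole-slide cell map: slide extent, per-class
#' cell counts, spatial clustering of cell positions (a Thomas cluster
#' process, or uniform), the distributions of nuclear shape factor and
#' area, and planted circular diversification zones in which the spread
#' of the shape factor is inflated and lymphocytes optionally depleted.
#'
#' Defaults are desk-scale: a 5 x 5 mm slide with 20,000 cancer cells,
#' 3,800 lymphocytes and 4,300 stromal cells (class proportions matching
#' large H&E cohort averages, scaled down by roughly a factor of nine),
#' and three planted circles of radius 250 um with shape-variability
#' multiplier 3 and no lymphocyte depletion. The per-cell shape factor
#' is `s = 1 + exp(N(base_logshape_mean, base_logshape_sd))`, i.e.
#' `s - 1` is lognormal, guaranteeing `s >= 1`; inside a planted zone
#' the Gaussian sd is multiplied by the zone's `variance_multiplier`,
#' inflating the spread (not the floor) of `s`. The nuclear area is
#' lognormal; the perimeter is back-computed as
#' `p = s * 2 * sqrt(pi * a)`, so each generated cell's true shape
#' factor is exact.
#'
#' @param width,height slide extent in um.
#' @param n_cancer,n_lymphocyte,n_stromal cell counts.
#' @param clustering `"thomas"` (default) or `"uniform"`.
#' @param parent_intensity Thomas parent intensity per um^2.
#' @param cluster_sd Gaussian dispersion of offspring around parents, um.
#' @param base_logshape_mean,base_logshape_sd parameters of
#'   `log(s - 1)`. Defaults give a median shape factor of about 1.15
#'   with an interquartile range of roughly 1.10-1.22, typical of
#'   segmented tumor nuclei.
#' @param nucleus_area_logmean,nucleus_area_logsd lognormal nuclear
#'   area parameters; defaults give a median of about 40 um^2.
#' @param planted_zones data frame with columns `x`, `y`, `radius`,
#'   `variance_multiplier` (>= 1), `lymphocyte_depletion` (in `[0,1]`),
#'   or `NULL` for a null slide. The default plants three circles.
#' @param rng_seed integer seed; the generated table is byte-identical
#'   for identical config + seed.
#' @return list of class `slide_config`.
#' @export
slide_config <- function(width = 5000, height = 5000,
                         n_cancer = 20000, n_lymphocyte = 3800,
                         n_stromal = 4300,
                         clustering = c("thomas", "uniform"),
                         parent_intensity = 2e-6, cluster_sd = 150,
                         base_logshape_mean = log(0.15),
                         base_logshape_sd = 0.35,
                         nucleus_area_logmean = log(40),
                         nucleus_area_logsd = 0.35,
                         planted_zones = default_planted_zones(width, height),
                         rng_seed = 1L) {
  clustering <- match.arg(clustering)
  stopifnot(width > 0, height > 0, n_cancer >= 0, n_lymphocyte >= 0,
            n_stromal >= 0)
  if (!is.null(planted_zones)) {
    planted_zones <- as.data.frame(planted_zones)
    stopifnot(all(c("x", "y", "radius", "variance_multiplier",
                    "lymphocyte_depletion") %in% names(planted_zones)))
    if (any(planted_zones$radius <= 0))
      stop("planted zone radius must be positive", call. = FALSE)
    if (any(planted_zones$variance_multiplier < 1))
      stop("variance_multiplier must be >= 1", call. = FALSE)
    if (any(planted_zones$lymphocyte_depletion < 0 |
            planted_zones$lymphocyte_depletion > 1))
      stop("lymphocyte_depletion must lie in [0, 1]", call. = FALSE)
    out_of_bounds <- planted_zones$x - planted_zones$radius < 0 |
      planted_zones$x + planted_zones$radius > width |
      planted_zones$y - planted_zones$radius < 0 |
      planted_zones$y + planted_zones$radius > height
    if (any(out_of_bounds))
      stop("planted zone(s) extend outside the slide bounds", call. = FALSE)
  }
  structure(list(
    width = width, height = height,
    n_cancer = as.integer(n_cancer),
    n_lymphocyte = as.integer(n_lymphocyte),
    n_stromal = as.integer(n_stromal),
    clustering = clustering, parent_intensity = parent_intensity,
    cluster_sd = cluster_sd,
    base_logshape_mean = base_logshape_mean,
    base_logshape_sd = base_logshape_sd,
    nucleus_area_logmean = nucleus_area_logmean,
    nucleus_area_logsd = nucleus_area_logsd,
    planted_zones = planted_zones,
    rng_seed = as.integer(rng_seed)
  ), class = "slide_config")
}

#' @rdname slide_config
#' @param variance_multiplier,lymphocyte_depletion values applied to all
#'   three default circles.
#' @export
default_planted_zones <- function(width = 5000, height = 5000,
                                  variance_multiplier = 3,
                                  lymphocyte_depletion = 0) {
  data.frame(
    x = c(0.25, 0.75, 0.5) * width,
    y = c(0.25, 0.25, 0.75) * height,
    radius = 250,
    variance_multiplier = variance_multiplier,
    lymphocyte_depletion = lymphocyte_depletion)
}

# Positions for n cells: Thomas cluster process fitted to an exact
# count (parents Poisson, offspring multinomial over parents, Gaussian
# dispersion, resampled into bounds), or uniform.
.sim_positions <- function(n, config) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (config$clustering == "uniform") {
    return(cbind(x = stats::runif(n, 0, config$width),
                 y = stats::runif(n, 0, config$height)))
  }
  area <- config$width * config$height
  n_parents <- max(1L, stats::rpois(1L, config$parent_intensity * area))
  px <- stats::runif(n_parents, 0, config$width)
  py <- stats::runif(n_parents, 0, config$height)
  parent <- sample.int(n_parents, n, replace = TRUE)
  x <- px[parent] + stats::rnorm(n, 0, config$cluster_sd)
  y <- py[parent] + stats::rnorm(n, 0, config$cluster_sd)
  bad <- which(x < 0 | x > config$width | y < 0 | y > config$height)
  while (length(bad)) {
    x[bad] <- px[parent[bad]] + stats::rnorm(length(bad), 0, config$cluster_sd)
    y[bad] <- py[parent[bad]] + stats::rnorm(length(bad), 0, config$cluster_sd)
    bad <- bad[x[bad] < 0 | x[bad] > config$width |
               y[bad] < 0 | y[bad] > config$height]
  }
  cbind(x = x, y = y)
}

# Index of the planted circle containing each point (0 = none; with
# overlapping circles, the one with the largest variance multiplier).
.in_planted <- function(x, y, zones) {
  if (is.null(zones) || nrow(zones) == 0L) return(integer(length(x)))
  hit <- integer(length(x))
  best <- rep(-Inf, length(x))
  for (k in seq_len(nrow(zones))) {
    inside <- (x - zones$x[k])^2 + (y - zones$y[k])^2 <= zones$radius[k]^2
    take <- inside & zones$variance_multiplier[k] > best
    hit[take] <- k
    best[take] <- zones$variance_multiplier[k]
  }
  hit
}

#' Generate a synthetic slide
#'
#' Draws cell positions, classes, and nuclear measurements according to
#' a [slide_config()], returning the cell table together with the
#' ground truth needed to evaluate zone recovery. Cell counts match the
#' config exactly before lymphocyte depletion; lymphocytes falling
#' inside a planted circle are then removed independently with the
#' circle's `lymphocyte_depletion` probability.
#'
#' @param config a [slide_config()].
#' @return list with `cells` (a [cell_table()]) and `truth` (class
#'   `slide_truth`: the planted circle geometries, the per-cell
#'   in-planted flag aligned with the rows of `cells`, the per-cell
#'   true shape factor, and the slide id).
#' @export
simulate_slide <- function(config) {
  stopifnot(inherits(config, "slide_config"))
  .with_seed(config$rng_seed, {
    classes <- rep(c("cancer", "lymphocyte", "stromal"),
                   c(config$n_cancer, config$n_lymphocyte, config$n_stromal))
    n <- length(classes)
    pos <- .sim_positions(n, config)
    zone_hit <- .in_planted(pos[, 1L], pos[, 2L], config$planted_zones)
    mult <- rep(1, n)
    if (!is.null(config$planted_zones) && nrow(config$planted_zones))
      mult[zone_hit > 0] <-
        config$planted_zones$variance_multiplier[zone_hit[zone_hit > 0]]
    s <- 1 + exp(stats::rnorm(n, config$base_logshape_mean,
                              config$base_logshape_sd * mult))
    a <- stats::rlnorm(n, config$nucleus_area_logmean,
                       config$nucleus_area_logsd)
    p <- s * 2 * sqrt(pi * a)
    keep <- rep(TRUE, n)
    if (!is.null(config$planted_zones) && nrow(config$planted_zones)) {
      lym_in <- which(classes == "lymphocyte" & zone_hit > 0)
      if (length(lym_in)) {
        dep <- config$planted_zones$lymphocyte_depletion[zone_hit[lym_in]]
        keep[lym_in] <- stats::runif(length(lym_in)) >= dep
      }
    }
    cells <- cell_table(data.frame(
      cell_id = sprintf("c%06d", seq_len(n)[keep]),
      x = pos[keep, 1L], y = pos[keep, 2L],
      cell_class = classes[keep],
      nucleus_area = a[keep],
      nucleus_perimeter = p[keep],
      stringsAsFactors = FALSE), slide_id = "synthetic")
    truth <- structure(list(
      planted_zones = config$planted_zones,
      in_planted = zone_hit[keep] > 0,
      true_shape_factor = s[keep],
      slide_id = "synthetic"), class = "slide_truth")
    list(cells = cells, truth = truth)
  })
}

#' Label zones against planted ground truth
#'
#' A zone is labelled `TRUE` when the fraction of its target-class cells
#' lying inside any planted circle reaches `overlap_threshold`.
#'
#' @param zone_map a [build_zone_map()] result built on the generated
#'   table.
#' @param truth the `truth` component of [simulate_slide()].
#' @param cells the generated [cell_table()].
#' @param overlap_threshold fraction in `(0, 1]` (default 0.5).
#' @param target_class class counted (default `"cancer"`).
#' @return named logical vector, one element per zone.
#' @export
match_zones_to_truth <- function(zone_map, truth, cells,
                                 overlap_threshold = 0.5,
                                 target_class = "cancer") {
  if (!identical(zone_map$slide_id, truth$slide_id))
    stop("zone map and ground truth come from different slides",
         call. = FALSE)
  stopifnot(nrow(cells) == length(truth$in_planted))
  sel <- cells$cell_class == target_class
  zid <- factor(zone_map$assignment$zone_id, levels = zone_map$seeds$zone_id)
  n_in <- tapply(truth$in_planted[sel], zid[sel], sum)
  n_tot <- tapply(rep(1L, sum(sel)), zid[sel], sum)
  frac <- ifelse(is.na(n_tot) | n_tot == 0, 0,
                 as.numeric(n_in) / as.numeric(n_tot))
  stats::setNames(frac >= overlap_threshold, zone_map$seeds$zone_id)
}

#' Confusion-matrix recovery metrics
#'
#' @param predicted,truth aligned logical vectors of per-zone calls and
#'   planted labels.
#' @return list with `sensitivity`, `specificity`, `precision`, `f1`;
#'   ratios with zero denominators are `NA`, not 0.
#' @export
recovery_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth labels differ in length", call. = FALSE)
  tp <- sum(predicted & truth); fn <- sum(!predicted & truth)
  fp <- sum(predicted & !truth); tn <- sum(!predicted & !truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

#' Write the synthetic ground truth sidecar
#'
#' Emits the planted circles as GeoJSON (circles approximated by
#' 64-gon polygons) and the per-cell flags as JSON.
#'
#' @param truth the `truth` component of [simulate_slide()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  zones <- truth$planted_zones
  features <- list()
  if (!is.null(zones) && nrow(zones)) {
    theta <- seq(0, 2 * pi, length.out = 65L)
    features <- lapply(seq_len(nrow(zones)), function(k) {
      ring <- lapply(theta, function(t)
        c(zones$x[k] + zones$radius[k] * cos(t),
          zones$y[k] + zones$radius[k] * sin(t)))
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = list(
             variance_multiplier = zones$variance_multiplier[k],
             lymphocyte_depletion = zones$lymphocyte_depletion[k]))
    })
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file.path(dir, "planted_zones.geojson"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(slide_id = truth$slide_id,
                            in_planted = truth$in_planted),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
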