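#' Nuclear shape factor
#'
#' The shape factor of a nucleus with perimeter `p` and area `a` is
#' `s = p / (2 * sqrt(pi * a))`: the ratio of the observed perimeter to
#' the perimeter of the circle with the same area. By the isoperimetric
#' inequality `s >= 1`, with equality for a perfect circle; larger
#' values indicate a more irregular (less circular) nucleus.
#'
#' @param perimeter nuclear perimeter (um), positive.
#' @param area nuclear area (um^2), positive.
#' @return numeric vector of shape factors.
#' @examples
#' shape_factor(2 * pi * 5, pi * 25)  # circle of radius 5 -> 1
#' shape_factor(4, 1)                 # unit square -> 2/sqrt(pi)
#' @export
shape_factor <- function(perimeter, area) {
  if (any(!is.finite(perimeter)) || any(!is.finite(area)) ||
      any(perimeter <= 0) || any(area <= 0))
    stop("perimeter and area must be positive and finite", call. = FALSE)
  perimeter / (2 * sqrt(pi * area))
}

#' Zonal shape variability
#'
#' For each zone, the variability statistic Y is the sample standard
#' deviation (n - 1 denominator) of the nuclear shape factors of the
#' zone's cells of the target class. Zones with fewer than
#' `min_cells` such cells carry too little information for a standard
#' deviation and are marked excluded; excluded zones are dropped from
#' the spatial test (and from the weights graph) downstream.
#'
#' @param zone_map a [build_zone_map()] result.
#' @param table the [cell_table()] the map was built on.
#' @param min_cells minimum number of target-class cells per zone
#'   (default 2).
#' @param target_class cell class whose nuclei are analysed.
#' @return data frame with one row per zone: `zone_id`, `n_target`,
#'   `Y`, `excluded`, `reason`.
#' @export
zone_variability <- function(zone_map, table, min_cells = 2L,
                             target_class = "cancer") {
  if (min_cells < 2L) stop("min_cells must be at least 2", call. = FALSE)
  sel <- table$cell_class == target_class
  s <- rep(NA_real_, nrow(table))
  s[sel] <- shape_factor(table$nucleus_perimeter[sel], table$nucleus_area[sel])
  zid <- zone_map$assignment$zone_id
  zone_ids <- zone_map$seeds$zone_id
  n_target <- as.integer(table(factor(zid[sel], levels = zone_ids)))
  Y <- rep(NA_real_, length(zone_ids))
  ok <- n_target >= min_cells
  if (any(ok)) {
    sd_by <- tapply(s[sel], factor(zid[sel], levels = zone_ids), stats::sd)
    Y[ok] <- as.numeric(sd_by[ok])
  }
  data.frame(zone_id = zone_ids, n_target = n_target, Y = Y,
             excluded = !ok,
             reason = ifelse(ok, "", sprintf("fewer than %d %s cells",
                                             min_cells, target_class)),
             stringsAsFactors = FALSE)
}

#' Local Moran's I on zone values
#'
#' The local Moran statistic for zone i is
#' `I_i = (Y_i - Ybar) * sum_j w_ij (Y_j - Ybar)` over the binary
#' queen-contiguity weights: a cross-product of the zone's own deviation
#' from the mean with the summed deviations of its neighbors. Positive
#' values indicate a zone embedded in similarly-deviating neighborhood
#' (hotspot/coldspot); negative values indicate a spatial outlier.
#' `mean_mode` selects the reference mean Ybar: `"global"` (the mean of
#' Y over all zones, the conventional LISA form and the default) or
#' `"neighborhood"` (zone-specific mean over the zone and its
#' neighbors; taking the neighbors alone would make the statistic
#' vanish identically, see Details in the methods vignette). Zones with
#' no neighbors get `I = 0` and are flagged isolated.
#'
#' @param Y numeric vector of zone values.
#' @param W a [neighbor_graph()] result aligned with `Y` (same order).
#' @param mean_mode `"global"` or `"neighborhood"`.
#' @return data frame with `I`, `isolated` and the attribute `Y_mean`
#'   (global mean; NA in neighborhood mode).
#' @export
local_morans_i <- function(Y, W, mean_mode = c("global", "neighborhood")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(length(Y) == length(W$zone_ids))
  if (anyNA(Y)) stop("Y must be defined on all zones passed to the test",
                     call. = FALSE)
  w <- W$w
  if (mean_mode == "global") {
    mu <- rep(mean(Y), length(Y))
    lag <- as.numeric(w %*% (Y - mu))
  } else {
    # closed neighborhood (zone plus its neighbors): with the open
    # neighborhood the lag term would vanish identically, since
    # deviations of the neighbors from their own mean sum to zero
    mu <- (as.numeric(w %*% Y) + Y) / (W$degree + 1)
    lag <- vapply(seq_along(Y), function(i)
      sum(w[i, ] * (Y - mu[i])), numeric(1))
  }
  I <- (Y - mu) * lag
  isolated <- W$degree == 0
  I[isolated] <- 0
  out <- data.frame(zone_id = W$zone_ids, I = I, isolated = isolated,
                    stringsAsFactors = FALSE)
  attr(out, "Y_mean") <- if (mean_mode == "global") mean(Y) else NA_real_
  out
}

#' Analytic moments and z-score of local Moran's I
#'
#' Expectation and variance of each `I_i` under conditional
#' randomization: zone i's value is held fixed while the remaining
#' values are randomly permuted over the remaining zones. With binary
#' weights the neighbor sum is then the total of a simple random sample
#' of size `w_i` drawn without replacement from the other zones'
#' deviations, giving closed forms
#' `E[I_i] = -w_i (Y_i - Ybar)^2 / (n - 1)` and
#' `Var[I_i] = (Y_i - Ybar)^2 * w_i * s2_i * (n - 1 - w_i) / (n - 2)`
#' where `s2_i` is the population variance of the other zones'
#' deviations. The standardized statistic `z_i = (I_i - E[I_i]) /
#' sqrt(Var[I_i])` is compared with the standard normal. Only defined
#' for `mean_mode = "global"`.
#'
#' @inheritParams local_morans_i
#' @param tail `"two_sided"` (default) or `"upper"` for the analytic p.
#' @return data frame with `I`, `E_I`, `Var_I`, `z`, `p_analytic`;
#'   zones where the variance vanishes (isolated zones, or all other
#'   values equal) get `NA` z and p.
#' @export
analytic_moments <- function(Y, W, tail = c("two_sided", "upper")) {
  tail <- match.arg(tail)
  n <- length(Y)
  stopifnot(length(W$zone_ids) == n)
  if (n < 4L)
    stop("analytic moments require at least 4 zones", call. = FALSE)
  li <- local_morans_i(Y, W, mean_mode = "global")
  zdev <- Y - mean(Y)
  k <- W$degree
  E_I <- -k * zdev^2 / (n - 1)
  Var_I <- numeric(n)
  for (i in seq_len(n)) {
    others <- zdev[-i]
    N <- n - 1L
    mu <- mean(others)
    s2 <- mean(others^2) - mu^2        # population variance of the pool
    Var_I[i] <- zdev[i]^2 * k[i] * s2 * (N - k[i]) / (N - 1)
  }
  Var_I[W$degree == 0] <- 0
  E_I[W$degree == 0] <- 0
  z <- ifelse(Var_I > 0, (li$I - E_I) / sqrt(Var_I), NA_real_)
  p <- switch(tail,
              two_sided = 2 * stats::pnorm(-abs(z)),
              upper = stats::pnorm(z, lower.tail = FALSE))
  data.frame(zone_id = W$zone_ids, I = li$I, E_I = E_I, Var_I = Var_I,
             z = z, p_analytic = p, isolated = li$isolated,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo (Hope) significance for local Moran's I
#'
#' Conditional-permutation p-values: for each zone, the other zones'
#' values are repeatedly re-drawn without replacement and the local
#' Moran statistic recomputed. The Hope add-one estimator
#' `p = (1 + #extreme) / (1 + n_permutations)` avoids zero p-values.
#' Two-sided extremeness compares `|I*| >= |I_observed|`.
#'
#' @inheritParams local_morans_i
#' @param n_permutations number of conditional permutations (>= 99).
#' @param tail `"two_sided"` or `"upper"`.
#' @param rng_seed optional seed for reproducibility.
#' @return numeric vector of empirical p-values, one per zone (isolated
#'   zones get `NA`).
#' @export
permutation_null <- function(Y, W, n_permutations = 999L,
                             tail = c("two_sided", "upper"),
                             rng_seed = NULL) {
  tail <- match.arg(tail)
  if (n_permutations < 99L)
    stop("n_permutations must be at least 99", call. = FALSE)
  n <- length(Y)
  stopifnot(length(W$zone_ids) == n)
  li <- local_morans_i(Y, W, mean_mode = "global")
  zdev <- Y - mean(Y)
  k <- W$degree
  .with_seed(rng_seed, {
    p <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (k[i] == 0) next
      others <- zdev[-i]
      Istar <- vapply(seq_len(n_permutations), function(b)
        zdev[i] * sum(others[sample.int(n - 1L, k[i])]), numeric(1))
      extreme <- if (tail == "two_sided") sum(abs(Istar) >= abs(li$I[i]) - 1e-12)
                 else sum(Istar >= li$I[i] - 1e-12)
      p[i] <- (1 + extreme) / (1 + n_permutations)
    }
    p
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, order-preserving with the
#' input indexing. Thin wrapper validating its input.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed for
#'   excluded zones; NAs propagate).
#' @return adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Diversification parameters
#'
#' Bundles the tunable parameters of the zone-level diversification
#' test.
#'
#' @param min_cancer_cells_per_zone minimum target-class cells for a
#'   zone to enter the test (default 2).
#' @param mean_mode reference mean in the local Moran statistic
#'   (`"global"` default; see [local_morans_i()]).
#' @param alpha significance level on the FDR-adjusted p (default 0.05).
#' @param tail `"two_sided"` (default) or `"upper"`.
#' @param flag_rule `"significant_and_high"` (default: q < alpha AND
#'   zone Y above the global mean, so flagged zones are high-variability
#'   zones whether hotspots or spatial outliers) or `"significant_any"`.
#' @param p_source which p-value feeds the FDR adjustment:
#'   `"analytic"` (default, the normal approximation the moments
#'   support) or `"permutation"` (Hope Monte-Carlo).
#' @param n_permutations permutations for the Hope p (used when
#'   requested; default 999).
#' @param target_class cell class analysed (default `"cancer"`).
#' @return list of class `div_params`.
#' @export
div_params <- function(min_cancer_cells_per_zone = 2L,
                       mean_mode = c("global", "neighborhood"),
                       alpha = 0.05,
                       tail = c("two_sided", "upper"),
                       flag_rule = c("significant_and_high", "significant_any"),
                       p_source = c("analytic", "permutation"),
                       n_permutations = 999L,
                       target_class = "cancer") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (min_cancer_cells_per_zone < 2L)
    stop("min_cancer_cells_per_zone must be >= 2", call. = FALSE)
  structure(list(
    min_cancer_cells_per_zone = as.integer(min_cancer_cells_per_zone),
    mean_mode = match.arg(mean_mode),
    alpha = alpha,
    tail = match.arg(tail),
    flag_rule = match.arg(flag_rule),
    p_source = match.arg(p_source),
    n_permutations = as.integer(n_permutations),
    target_class = target_class
  ), class = "div_params")
}

#' Flag diversified zones
#'
#' Applies the diversification call to a zone results table: under the
#' default rule a zone is diversified when its FDR-adjusted p falls
#' below `alpha` AND its variability Y exceeds the global mean, so that
#' calls always point at zones of elevated (not depressed) shape
#' variability. The alternative rule flags on significance alone.
#'
#' @param results data frame containing at least `q` and `Y` columns.
#' @param params a [div_params()].
#' @param Y_mean global mean of Y over the tested zones.
#' @return `results` with a logical `diversified` column.
#' @export
flag_diversified <- function(results, params, Y_mean) {
  sig <- !is.na(results$q) & results$q < params$alpha
  flag <- if (params$flag_rule == "significant_and_high")
    sig & !is.na(results$Y) & results$Y > Y_mean
  else sig
  results$diversified <- flag
  results
}

#' Summarize a slide from its zone results
#'
#' @param results zone results data frame with `diversified` and
#'   `excluded` columns.
#' @param slide_id slide identifier.
#' @return one-row data frame: `slide_id`, `m_zones` (non-excluded),
#'   `n_diversified`, `fraction_diversified`, `present` (at least one
#'   diversified zone).
#' @export
summarize_sample <- function(results, slide_id = "slide") {
  m <- sum(!results$excluded)
  nd <- sum(results$diversified, na.rm = TRUE)
  data.frame(slide_id = slide_id, m_zones = m, n_diversified = nd,
             fraction_diversified = if (m > 0) nd / m else NA_real_,
             present = nd >= 1L, stringsAsFactors = FALSE)
}
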