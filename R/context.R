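#' Zonal cell composition
#'
#' Per-zone counts and fractions of the three cell classes. Fractions
#' are over all cells assigned to the zone, so the three fractions sum
#' to one.
#'
#' @param zone_map a [build_zone_map()] result.
#' @param table the [cell_table()] the map was built on.
#' @return data frame: `zone_id`, `n_cancer`, `n_lymphocyte`,
#'   `n_stromal`, `tumor_fraction`, `lymphocyte_fraction`,
#'   `stromal_fraction`.
#' @export
zone_composition <- function(zone_map, table) {
  zid <- factor(zone_map$assignment$zone_id, levels = zone_map$seeds$zone_id)
  cls <- factor(table$cell_class, levels = .known_classes)
  counts <- table(zid, cls)
  tot <- rowSums(counts)
  data.frame(
    zone_id = zone_map$seeds$zone_id,
    n_cancer = as.integer(counts[, "cancer"]),
    n_lymphocyte = as.integer(counts[, "lymphocyte"]),
    n_stromal = as.integer(counts[, "stromal"]),
    tumor_fraction = ifelse(tot > 0, counts[, "cancer"] / tot, NA_real_),
    lymphocyte_fraction = ifelse(tot > 0, counts[, "lymphocyte"] / tot, NA_real_),
    stromal_fraction = ifelse(tot > 0, counts[, "stromal"] / tot, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Zonal spatial groups around diversified zones
#'
#' Partitions zones into three ordered groups: 1 = diversified zones,
#' 2 = their immediately adjacent non-diversified neighbors, 3 = all
#' remaining zones. Group 1 takes precedence: a diversified zone
#' neighboring another diversified zone stays in group 1.
#'
#' The returned factor is ordered `rest < adjacent < diversified`,
#' i.e. by spatial proximity to a diversified zone, so that
#' [jonckheere_test()] with `alternative = "decreasing"` directly tests
#' for values falling toward the diversified zones (e.g. local
#' lymphocyte depletion).
#'
#' @param flags logical vector of per-zone diversification calls,
#'   aligned with `W`.
#' @param W a [neighbor_graph()] result.
#' @return ordered factor (`rest` < `adjacent` < `diversified`), one
#'   element per zone, named by zone id.
#' @export
zonal_groups <- function(flags, W) {
  stopifnot(length(flags) == length(W$zone_ids))
  touches_flagged <- as.numeric(W$w %*% flags) > 0
  g <- ifelse(flags, 1L, ifelse(touches_flagged, 2L, 3L))
  stats::setNames(
    factor(c("diversified", "adjacent", "rest")[g],
           levels = c("rest", "adjacent", "diversified"), ordered = TRUE),
    W$zone_ids)
}

# Jonckheere-Terpstra statistic for the "increasing in group order"
# alternative: sum over ordered group pairs (k < l) of Mann-Whitney
# counts #(x_k < x_l) with ties counted 1/2.
.jt_statistic <- function(values, group_idx, k) {
  J <- 0
  for (g1 in seq_len(k - 1L)) {
    a <- values[group_idx == g1]
    for (g2 in (g1 + 1L):k) {
      b <- values[group_idx == g2]
      # Mann-Whitney count #(a < b) via midranks, ties half-counted
      r <- rank(c(a, b))
      U <- sum(r[(length(a) + 1L):(length(a) + length(b))]) -
        length(b) * (length(b) + 1L) / 2
      J <- J + U
    }
  }
  J
}

#' Jonckheere-Terpstra trend test across ordered zone groups
#'
#' Tests for a monotone trend of a zonal quantity (e.g. lymphocyte
#' fraction) across ordered groups, typically the
#' diversified < adjacent < rest partition of [zonal_groups()]. The
#' statistic is the sum over ordered group pairs of Mann-Whitney
#' counts, ties counted one half. The alternative describes the trend
#' along the factor's level order: `"increasing"` tests for values
#' rising from the first level to the last, `"decreasing"` (the
#' default) for values falling along it — with [zonal_groups()]'s
#' `rest < adjacent < diversified` ordering, the default tests
#' lymphocyte depletion toward the diversified zones. Internally large
#' J always favors the stated alternative.
#'
#' The p-value comes either from the normal approximation with
#' tie-corrected variance, or from random permutation of the group
#' labels with the Hope add-one estimator.
#'
#' @param values numeric vector.
#' @param groups ordered factor (or anything coercible) giving each
#'   value's group; group order defines the trend direction.
#' @param method `"normal_approx"` (default) or `"permutation"`.
#' @param alternative `"decreasing"` (default) or `"increasing"`.
#' @param n_permutations permutations for `method = "permutation"`.
#' @param rng_seed optional seed for the permutation method.
#' @return list with `J` (statistic, oriented so large favors the
#'   alternative), `p`, `method`, `alternative`.
#' @export
jonckheere_test <- function(values, groups,
                            method = c("normal_approx", "permutation"),
                            alternative = c("decreasing", "increasing"),
                            n_permutations = 999L, rng_seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  lev <- levels(groups)
  lev <- lev[lev %in% unique(as.character(groups))]
  if (length(lev) < 2L)
    stop("jonckheere test needs at least 2 non-empty groups", call. = FALSE)
  if (alternative == "decreasing") lev <- rev(lev)
  gidx <- match(as.character(groups), lev)
  k <- length(lev)
  J <- .jt_statistic(values, gidx, k)
  n <- length(values)
  ni <- tabulate(gidx, k)
  if (method == "normal_approx") {
    tj <- as.numeric(table(values))   # tie group sizes
    EJ <- (n^2 - sum(ni^2)) / 4
    A <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
    C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
    V <- A / 72 + B / (36 * n * (n - 1) * (n - 2)) + C / (8 * n * (n - 1))
    if (V <= 0) {
      p <- 1
    } else {
      p <- stats::pnorm((J - EJ) / sqrt(V), lower.tail = FALSE)
    }
    list(J = J, p = p, method = method, alternative = alternative)
  } else {
    pval <- .with_seed(rng_seed, {
      Jstar <- vapply(seq_len(n_permutations), function(b)
        .jt_statistic(values, sample(gidx), k), numeric(1))
      (1 + sum(Jstar >= J - 1e-12)) / (1 + n_permutations)
    })
    list(J = J, p = pval, method = method, alternative = alternative)
  }
}

#' Zone-level marker values from per-cell scores
#'
#' Mean `marker_value` over each zone's cells (the cell-level analogue
#' of scoring all marker-positive pixels inside a zone polygon).
#'
#' @param zone_map a [build_zone_map()] result.
#' @param table a [cell_table()] carrying a `marker_value` column.
#' @return named numeric vector, one value per zone (NaN for empty
#'   zones).
#' @export
zone_marker_values <- function(zone_map, table) {
  if (is.null(table$marker_value))
    stop("cell table has no marker_value column; zone-level marker ",
         "analysis requires per-cell marker scores", call. = FALSE)
  zid <- factor(zone_map$assignment$zone_id, levels = zone_map$seeds$zone_id)
  out <- tapply(table$marker_value, zid, mean)
  stats::setNames(as.numeric(out), zone_map$seeds$zone_id)
}

#' Zone-level marker correlation with tumor-content filter
#'
#' Spearman rank correlation between two zonal quantities, restricted
#' to zones of intermediate tumor content (default: tumor fraction
#' between 30% and 70% inclusive) so that the correlation is not driven
#' by zones that are nearly pure tumor or nearly pure stroma.
#'
#' @param values_a,values_b numeric vectors on a common zone set.
#' @param composition [zone_composition()] result for the same zones.
#' @param tumor_fraction_range inclusive filter bounds.
#' @return list with `rho` (Spearman) and `n_zones_used`.
#' @export
zone_marker_correlation <- function(values_a, values_b, composition,
                                    tumor_fraction_range = c(0.30, 0.70)) {
  stopifnot(length(values_a) == length(values_b),
            length(values_a) == nrow(composition))
  tf <- composition$tumor_fraction
  keep <- !is.na(tf) & tf >= tumor_fraction_range[1] &
    tf <= tumor_fraction_range[2] & !is.na(values_a) & !is.na(values_b)
  if (sum(keep) < 3L)
    stop("fewer than 3 zones survive the tumor-content filter",
         call. = FALSE)
  list(rho = stats::cor(values_a[keep], values_b[keep], method = "spearman"),
       n_zones_used = sum(keep))
}
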