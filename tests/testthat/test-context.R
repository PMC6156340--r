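test_that("zone composition gives exact counts and conserved totals", {
  tab <- make_cells(x = c(1, 2, 3, 4, 60, 61), y = rep(0, 6),
                    class = c("cancer", "cancer", "cancer", "lymphocyte",
                              "cancer", "stromal"))
  zm <- build_zone_map(tab, seeds = c("c001", "c005"),
                       tissue_polygon = cbind(c(0, 62, 62, 0),
                                              c(-1, -1, 1, 1)))
  comp <- zone_composition(zm, tab)
  expect_equal(comp$tumor_fraction[1], 0.75)
  expect_equal(comp$lymphocyte_fraction[1], 0.25)
  expect_equal(comp$tumor_fraction[2], 0.5)
  expect_equal(comp$n_cancer + comp$n_lymphocyte + comp$n_stromal,
               c(4L, 2L))
  # conservation against slide totals on a simulated slide
  sim <- small_slide(seed = 14)
  zm2 <- build_zone_map(sim$cells, select_seeds(sim$cells, 30, rng_seed = 14))
  comp2 <- zone_composition(zm2, sim$cells)
  expect_identical(sum(comp2$n_cancer),
                   sum(sim$cells$cell_class == "cancer"))
  expect_identical(sum(comp2$n_lymphocyte),
                   sum(sim$cells$cell_class == "lymphocyte"))
  expect_equal(comp2$tumor_fraction + comp2$lymphocyte_fraction +
                 comp2$stromal_fraction, rep(1, 30))
})

test_that("zonal groups partition zones into diversified/adjacent/rest", {
  # chain A-B-C-D-E with only A flagged -> (1,2,3,3,3)
  w <- matrix(0L, 5, 5)
  for (i in 1:4) { w[i, i + 1] <- 1L; w[i + 1, i] <- 1L }
  W <- weights_from_matrix(w)
  g <- zonal_groups(c(TRUE, FALSE, FALSE, FALSE, FALSE), W)
  expect_identical(as.character(g),
                   c("diversified", "adjacent", "rest", "rest", "rest"))
  expect_true(is.ordered(g))
  expect_lt(which(levels(g) == "rest"), which(levels(g) == "diversified"))

  expect_identical(as.character(zonal_groups(rep(FALSE, 5), W)), rep("rest", 5))
  expect_identical(as.character(zonal_groups(rep(TRUE, 5), W)),
                   rep("diversified", 5))

  # diversified takes precedence over adjacency to another flagged zone
  g2 <- zonal_groups(c(TRUE, TRUE, FALSE, FALSE, FALSE), W)
  expect_identical(as.character(g2),
                   c("diversified", "diversified", "adjacent", "rest", "rest"))
  # output is always a partition
  expect_false(anyNA(g2))
})

test_that("jonckheere statistic: maximum, minimum and tie conventions", {
  g <- factor(rep(1:3, each = 2), ordered = TRUE)
  up <- jonckheere_test(c(1, 2, 3, 4, 5, 6), g, alternative = "increasing")
  expect_equal(up$J, 12)  # its maximum: 3 group pairs x 4 comparisons

  down <- jonckheere_test(c(6, 5, 4, 3, 2, 1), g, alternative = "increasing")
  expect_equal(down$J, 0)

  tied <- jonckheere_test(rep(1, 6), g, alternative = "increasing")
  expect_equal(tied$J, 6)  # half the 12 between-group pairs
  expect_equal(tied$p, 1)

  expect_error(jonckheere_test(1:4, factor(rep("a", 4))), "2 non-empty")
})

test_that("jonckheere permutation p matches exhaustive enumeration", {
  vals <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(1:3, each = 2), ordered = TRUE)
  # exhaustive oracle over all 6!/(2!2!2!) = 90 equal-size assignments
  perms <- combn(6, 2, simplify = FALSE)
  Js <- c()
  for (ab in perms) {
    rest <- setdiff(1:6, ab)
    for (cd in combn(rest, 2, simplify = FALSE)) {
      gi <- integer(6); gi[ab] <- 1L; gi[cd] <- 2L; gi[setdiff(rest, cd)] <- 3L
      Js <- c(Js, morphozone:::.jt_statistic(vals, gi, 3L))
    }
  }
  expect_identical(length(Js), 90L)
  expect_equal(max(Js), 12)
  exact_p <- mean(Js >= 12)
  expect_equal(exact_p, 1 / 90)

  hope <- jonckheere_test(vals, g, method = "permutation",
                          alternative = "increasing",
                          n_permutations = 9999, rng_seed = 2)
  expect_equal(hope$J, 12)
  expect_lt(abs(hope$p - exact_p), 0.01)
  expect_gte(hope$p, 1 / 10000)  # Hope lower bound
})

test_that("normal approximation converges to the permutation p", {
  set.seed(8)
  vals <- c(rnorm(40, 0), rnorm(40, 0.3), rnorm(40, 0.6))
  g <- factor(rep(1:3, each = 40), ordered = TRUE)
  pn <- jonckheere_test(vals, g, alternative = "increasing")$p
  pp <- jonckheere_test(vals, g, method = "permutation",
                        alternative = "increasing",
                        n_permutations = 4999, rng_seed = 3)$p
  expect_lt(abs(pn - pp), 3 * sqrt(pn * (1 - pn) / 4999) + 0.005)
})

test_that("decreasing alternative mirrors the group order", {
  vals <- c(5, 6, 3, 4, 1, 2)
  g <- factor(rep(1:3, each = 2), ordered = TRUE)
  dec <- jonckheere_test(vals, g, alternative = "decreasing")
  inc <- jonckheere_test(vals, g, alternative = "increasing")
  expect_equal(dec$J, 12)  # perfectly decreasing -> maximal for "decreasing"
  expect_equal(inc$J, 0)
  expect_lt(dec$p, 0.05)
})

test_that("marker correlation applies the inclusive tumor-content filter", {
  comp <- data.frame(tumor_fraction = c(0.2, 0.5, 0.9, 0.4, 0.6))
  a <- c(10, 1, 99, 2, 3)
  r <- zone_marker_correlation(a, a, comp)
  expect_identical(r$n_zones_used, 3L)  # 0.5, 0.4, 0.6 survive
  expect_equal(r$rho, 1)

  rev_r <- zone_marker_correlation(a, -a, comp)
  expect_equal(rev_r$rho, -1)

  # boundary values are included
  comp2 <- data.frame(tumor_fraction = c(0.30, 0.70, 0.5, 0.1))
  r2 <- zone_marker_correlation(1:4, 1:4, comp2)
  expect_identical(r2$n_zones_used, 3L)

  comp3 <- data.frame(tumor_fraction = c(0.1, 0.9, 0.95))
  expect_error(zone_marker_correlation(1:3, 1:3, comp3), "fewer than 3")
})

test_that("zone marker values need a marker column and average per zone", {
  tab <- make_cells(x = c(1, 2, 60), y = rep(0, 3))
  zm <- build_zone_map(tab, seeds = c("c001", "c003"),
                       tissue_polygon = cbind(c(0, 61, 61, 0),
                                              c(-1, -1, 1, 1)))
  expect_error(zone_marker_values(zm, tab), "marker_value")
  df <- as.data.frame(tab)
  df$marker_value <- c(0.2, 0.4, 0.9)
  tab2 <- cell_table(df, slide_id = "fixture")
  mv <- zone_marker_values(zm, tab2)
  expect_equal(unname(mv), c(0.3, 0.9))
})

test_that("planted lymphocyte depletion produces a detectable zonal trend", {
  # power of the decreasing-trend test rises with the depletion parameter
  pvals_for <- function(depletion, seeds) {
    vapply(seeds, function(s) {
      planted <- data.frame(x = c(400, 1100), y = c(400, 1100), radius = 320,
                            variance_multiplier = 3,
                            lymphocyte_depletion = depletion)
      sim <- small_slide(seed = s, planted = planted, n_lymphocyte = 1500)
      zm <- build_zone_map(sim$cells,
                           select_seeds(sim$cells, 90, rng_seed = s))
      W <- neighbor_graph(zm)
      truth <- match_zones_to_truth(zm, sim$truth, sim$cells,
                                    overlap_threshold = 0.5)
      comp <- zone_composition(zm, sim$cells)
      g <- zonal_groups(unname(truth), W)
      # a seed can leave the partition degenerate (no zone reaches the
      # overlap threshold); such slides carry no trend information
      if (sum(truth) == 0) return(NA_real_)
      jonckheere_test(comp$lymphocyte_fraction, g,
                      alternative = "decreasing")$p
    }, numeric(1))
  }
  seeds <- 1:6
  p_none <- pvals_for(0, seeds)
  p_strong <- pvals_for(0.9, seeds)
  expect_gt(mean(p_strong < 0.05, na.rm = TRUE),
            mean(p_none < 0.05, na.rm = TRUE))
  expect_lt(mean(p_strong, na.rm = TRUE), mean(p_none, na.rm = TRUE))
})
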