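test_that("shape factor closed forms: circle 1, square 2/sqrt(pi)", {
  r <- c(1, 5, 17.3)
  expect_equal(shape_factor(2 * pi * r, pi * r^2), rep(1, 3))
  expect_equal(shape_factor(4, 1), 2 / sqrt(pi))
  expect_error(shape_factor(10, 0), "positive")
  expect_error(shape_factor(-1, 5), "positive")
})

test_that("zonal variability is the sample SD of shape factors", {
  # one zone whose cells all share (p, a) -> Y = 0
  tab <- make_cells(x = c(0, 1, 2, 50, 51, 52), y = rep(0, 6),
                    area = 40, perimeter = 25)
  zm <- build_zone_map(tab, seeds = c("c001", "c004"),
                       tissue_polygon = cbind(c(-1, 53, 53, -1),
                                              c(-1, -1, 1, 1)))
  zv <- zone_variability(zm, tab)
  expect_equal(zv$Y, c(0, 0))

  # two-point zone: shape factors 1.0 and 1.2 -> sample SD
  a <- 40
  tab2 <- make_cells(x = c(0, 1, 50, 51), y = rep(0, 4), area = a,
                     perimeter = c(1.0, 1.2, 1.0, 1.3) * 2 * sqrt(pi * a))
  zm2 <- build_zone_map(tab2, seeds = c("c001", "c003"),
                        tissue_polygon = cbind(c(-1, 53, 53, -1),
                                               c(-1, -1, 1, 1)))
  zv2 <- zone_variability(zm2, tab2)
  expect_equal(zv2$Y[1], sd(c(1.0, 1.2)))
  expect_equal(zv2$Y[1], 0.1414, tolerance = 1e-3)

  # single-cell zone excluded under min_cells = 2
  tab3 <- make_cells(x = c(0, 1, 50), y = rep(0, 3))
  zm3 <- build_zone_map(tab3, seeds = c("c001", "c003"),
                        tissue_polygon = cbind(c(-1, 53, 53, -1),
                                               c(-1, -1, 1, 1)))
  zv3 <- zone_variability(zm3, tab3)
  expect_identical(zv3$excluded, c(FALSE, TRUE))
  expect_true(is.na(zv3$Y[2]))
  expect_error(zone_variability(zm3, tab3, min_cells = 1), "at least 2")
})

test_that("local Moran's I matches hand computation and brute force", {
  # constant Y -> I = 0 everywhere
  W4 <- weights_from_matrix(matrix(1, 4, 4) - diag(4))
  expect_equal(local_morans_i(rep(2.5, 4), W4)$I, rep(0, 4))

  # 2x2 all-mutually-adjacent, Y = (4,4,0,0), global mean 2
  li <- local_morans_i(c(4, 4, 0, 0), W4)
  expect_equal(li$I, c(-4, -4, -4, -4))

  # random instances vs a literal neighbor-list re-implementation
  for (seed in 1:3) {
    set.seed(seed)
    m <- sample(30:50, 1)
    w <- matrix(rbinom(m * m, 1, 0.15), m, m)
    w <- 1L * ((w + t(w)) > 0); diag(w) <- 0L
    Y <- rlnorm(m, -2, 0.5)
    W <- weights_from_matrix(w)
    ours <- local_morans_i(Y, W)$I
    Ybar <- mean(Y)
    brute <- vapply(seq_len(m), function(i) {
      nb <- which(w[i, ] == 1)
      (Y[i] - Ybar) * sum(Y[nb] - Ybar)
    }, numeric(1))
    brute[W$degree == 0] <- 0
    expect_equal(ours, brute, tolerance = 1e-12)
  }
})

test_that("neighborhood-mean mode uses each zone's closed-neighborhood mean", {
  # chain z1 - z2 - z3 with Y = (1, 5, 3), hand-computed closed means:
  # z1: mu = (1+5)/2 = 3 -> (1-3)*(5-3) = -4
  # z2: mu = (1+5+3)/3 = 3 -> (5-3)*((1-3)+(3-3)) = -4
  # z3: mu = (5+3)/2 = 4 -> (3-4)*(5-4) = -1
  w <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  W <- weights_from_matrix(w)
  li <- local_morans_i(c(1, 5, 3), W, mean_mode = "neighborhood")
  expect_equal(li$I, c(-4, -4, -1))
  # constant field still gives zero
  expect_equal(local_morans_i(rep(7, 3), W, mean_mode = "neighborhood")$I,
               rep(0, 3))
})

test_that("analytic moments: closed-form expectation and permutation oracle", {
  # E[I_1] = -w_1 (Y_1 - Ybar)^2 / (n-1) = -2 * 1.6^2 / 4 = -1.28
  w <- matrix(0L, 5, 5)
  w[1, 2] <- w[2, 1] <- 1L; w[1, 3] <- w[3, 1] <- 1L
  w[2, 3] <- w[3, 2] <- 1L; w[4, 5] <- w[5, 4] <- 1L
  W <- weights_from_matrix(w)
  Y <- c(3, 1, 1, 1, 1)
  am <- analytic_moments(Y, W)
  expect_equal(am$E_I[1], -2 * 1.6^2 / 4)

  # constant Y -> degenerate: E = 0, Var = 0, z undefined
  am0 <- analytic_moments(rep(1, 5), W)
  expect_equal(am0$E_I, rep(0, 5))
  expect_equal(am0$Var_I, rep(0, 5))
  expect_true(all(is.na(am0$z)))

  expect_error(analytic_moments(c(1, 2, 3), weights_from_matrix(
    matrix(0L, 3, 3))), "at least 4")

  # permutation oracle on a 20-zone instance (unit-test scale)
  set.seed(77)
  m <- 20
  w <- matrix(rbinom(m * m, 1, 0.2), m, m)
  w <- 1L * ((w + t(w)) > 0); diag(w) <- 0L
  W <- weights_from_matrix(w)
  Y <- rlnorm(m, -2, 0.4)
  am <- analytic_moments(Y, W)
  zd <- Y - mean(Y)
  B <- 10000
  for (i in c(1, 7, 13)) {
    k <- W$degree[i]
    Istar <- replicate(B, zd[i] * sum(sample(zd[-i], k)))
    se <- sd(Istar) / sqrt(B)
    expect_lt(abs(mean(Istar) - am$E_I[i]), 4 * se)
    expect_lt(abs(var(Istar) / am$Var_I[i] - 1), 0.1)
  }
})

test_that("under an exchangeable null the analytic p is near-uniform", {
  set.seed(31)
  pvals <- c()
  for (b in 1:30) {
    m <- 40
    w <- matrix(rbinom(m * m, 1, 0.15), m, m)
    w <- 1L * ((w + t(w)) > 0); diag(w) <- 0L
    Y <- rnorm(m)
    pvals <- c(pvals, analytic_moments(Y, weights_from_matrix(w))$p_analytic)
  }
  pvals <- pvals[!is.na(pvals)]
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 1e-4)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("Hope permutation p agrees with the analytic p and is bounded below", {
  # agreement is a large-sample property: at 200 zones the two routes
  # coincide within Monte-Carlo error and make the same calls
  set.seed(55)
  m <- 200
  w <- matrix(rbinom(m * m, 1, 0.04), m, m)
  w <- 1L * ((w + t(w)) > 0); diag(w) <- 0L
  W <- weights_from_matrix(w)
  Y <- rnorm(m)
  am <- analytic_moments(Y, W)
  pp <- permutation_null(Y, W, n_permutations = 1999, rng_seed = 1)
  ok <- !is.na(am$p_analytic)
  expect_lt(median(abs(pp[ok] - am$p_analytic[ok])), 0.03)
  small <- ok & am$p_analytic < 0.1
  se <- sqrt(pmax(am$p_analytic, 1e-3) * (1 - am$p_analytic) / 1999)
  expect_true(all(abs(pp[small] - am$p_analytic[small]) <
                    5 * se[small] + 0.02))
  expect_gt(mean((pp[ok] < 0.05) == (am$p_analytic[ok] < 0.05)), 0.95)
  expect_true(all(pp >= 1 / 2000, na.rm = TRUE))

  # constant Y -> permutation p = 1 everywhere
  p1 <- permutation_null(rep(2, m), W, n_permutations = 99, rng_seed = 1)
  expect_true(all(p1 == 1))

  # reproducible from rng_seed, and >= 99 permutations enforced
  expect_identical(pp, permutation_null(Y, W, n_permutations = 1999,
                                        rng_seed = 1))
  expect_error(permutation_null(Y, W, n_permutations = 10), "at least 99")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(fdr_adjust(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order-preserving with input indexing
  p <- c(0.04, 0.001, 0.9, 0.02)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
})

test_that("diversification flags require significance and elevated Y", {
  res <- data.frame(q = c(0.2, 0.2, 0.2), Y = c(1, 2, 3),
                    excluded = FALSE)
  params <- div_params()
  expect_false(any(flag_diversified(res, params, 2)$diversified))

  res2 <- data.frame(q = c(0.01, 0.01), Y = c(0.5, 3), excluded = FALSE)
  f <- flag_diversified(res2, params, 2)$diversified
  expect_identical(f, c(FALSE, TRUE))  # significant but low-Y not flagged

  params_any <- div_params(flag_rule = "significant_any")
  f2 <- flag_diversified(res2, params_any, 2)$diversified
  expect_identical(f2, c(TRUE, TRUE))
})

test_that("sample summaries report the present/absent call", {
  res <- data.frame(diversified = c(TRUE, TRUE, FALSE, FALSE),
                    excluded = rep(FALSE, 4))
  s <- summarize_sample(res, "s1")
  expect_identical(s$present, TRUE)
  expect_equal(s$fraction_diversified, 0.5)

  res0 <- data.frame(diversified = rep(FALSE, 500), excluded = rep(FALSE, 500))
  expect_false(summarize_sample(res0)$present)
  res1 <- res0; res1$diversified[1] <- TRUE
  s1 <- summarize_sample(res1)
  expect_true(s1$present)
  expect_equal(s1$fraction_diversified, 0.002)
})
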