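test_that("KDE density matches the closed form and the naive sum", {
  # single point at the query, one dimension, unit bandwidth: 1/sqrt(2 pi)
  X <- matrix(0, 1, 1)
  expect_equal(kde_density(0, 1, X, bandwidths = 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # far query: density vanishes
  expect_equal(kde_density(1e8, 1, X, bandwidths = 1), 0)

  for (seed in 1:5) {
    X <- random_fixture(seed, n = 20)
    h <- kde_bandwidths(X)
    q <- X[3, ] + 0.1
    for (S in list(1L, c(1L, 2L), seq_len(min(3L, ncol(X))))) {
      expect_equal(kde_density(q, S, X, h), naive_kde(q, S, X, h),
                   tolerance = 1e-12)
    }
  }
})

test_that("KDE integrates to 1 in one dimension", {
  set.seed(21)
  X <- matrix(rnorm(40, 2, 1.5), ncol = 1)
  h <- kde_bandwidths(X)
  grid <- seq(min(X) - 6 * h, max(X) + 6 * h, length.out = 4001)
  dens <- kde_density(matrix(grid, ncol = 1), 1L, X, h)
  integral <- sum(dens) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("bandwidths follow the normal-reference rule and are floored", {
  set.seed(31)
  X <- cbind(rnorm(50), rep(2, 50))
  expect_warning(h <- kde_bandwidths(X), "floored")
  expect_equal(h[1], 1.06 * sd(X[, 1]) * 50^(-1 / 5), tolerance = 1e-12)
  expect_gt(h[2], 0)
})

test_that("density rank follows the min-tie sort oracle", {
  set.seed(41)
  X <- matrix(rnorm(30), 15, 2)
  h <- kde_bandwidths(X)
  dens <- kde_density(X, c(1L, 2L), X, h)
  for (i in seq_len(15)) {
    rk <- density_rank(i, c(1L, 2L), X, bandwidths = h)
    expect_equal(rk$raw, rank(dens, ties.method = "min")[i])
    expect_equal(rk$outlyingness, -rk$raw)
  }
  # unique global minimum gets rank 1
  lone <- which.min(dens)
  expect_equal(density_rank(lone, c(1L, 2L), X, bandwidths = h)$raw, 1L)
  # all points identical: every rank is 1
  Xc <- matrix(1, 6, 2)
  expect_warning(rk_const <- density_rank(3, 1L, Xc), "floored")
  expect_equal(rk_const$raw, 1L)
})

test_that("density Z-score is the centred, population-scaled density", {
  set.seed(51)
  X <- matrix(rnorm(60), 30, 2)
  h <- kde_bandwidths(X)
  S <- c(1L, 2L)
  dens <- kde_density(X, S, X, h)
  mu <- mean(dens)
  sigma <- sqrt(mean((dens - mu)^2))
  z5 <- density_zscore(X[5, ], S, X, bandwidths = h)
  expect_equal(z5$raw, (dens[5] - mu) / sigma, tolerance = 1e-9)
  expect_equal(z5$orientation, "lower_is_outlying")
  # dataset mean of Z-scores is 0 in any subspace
  zs <- sapply(seq_len(30), function(i) {
    density_zscore(X[i, ], S, X, bandwidths = h, dens = dens)$raw
  })
  expect_lt(abs(mean(zs)), 1e-9)
})

test_that("sGrid counts agree with direct cell+neighbour enumeration", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 50
    X <- matrix(runif(n * 2, -3, 5), n, 2)
    queries <- rbind(X[1:5, ], c(-10, 10))  # include an out-of-range point
    for (qi in seq_len(nrow(queries))) {
      q <- queries[qi, ]
      for (S in list(1L, 2L, c(1L, 2L))) {
        d <- sgrid_density(q, S, X)
        expect_equal(as.integer(attr(d, "count")),
                     naive_sgrid_count(q, S, X),
                     info = sprintf("seed %d q %d |S|=%d", seed, qi,
                                    length(S)))
      }
    }
  }
})

test_that("sGrid density counts all points for a constant feature", {
  # a constant column collapses onto a single cell (bins span the data
  # range, which is empty), so any in-range query sees every point
  X <- matrix(rep(0.42, 30), ncol = 1)
  d <- sgrid_density(0.42, 1L, X)
  expect_equal(as.integer(attr(d, "count")), 30L)
  # an isolated corner query over an empty neighbourhood counts nothing
  X2 <- matrix(c(runif(29, 10, 11), 0), ncol = 1)
  d2 <- sgrid_density(0, 1L, X2)
  expect_equal(as.integer(attr(d2, "count")), 1L)  # only the corner point
})

test_that("sGrid Z-score averages to 0 over the dataset", {
  set.seed(61)
  X <- matrix(rnorm(80), 40, 2)
  zs <- sapply(seq_len(40), function(i) sgrid_zscore(X[i, ], c(1L, 2L), X)$raw)
  expect_lt(abs(mean(zs)), 1e-9)
})

test_that("iPath equals the isolation forest on the projected data", {
  set.seed(71)
  X <- matrix(rnorm(200), 50, 4)
  S <- c(2L, 4L)
  seed <- 17
  forest <- fit_iforest(X[, S], t = 50, psi = 16, seed = seed)
  q <- X[7, ]
  via_measure <- ipath_score(q, S, X, forest = forest)
  direct <- iforest_path_lengths(forest, matrix(q[S], 1))
  expect_equal(via_measure$raw, direct[[1]], tolerance = 1e-12)
  expect_equal(via_measure$outlyingness, -via_measure$raw)

  # psi = 2 trees have depth <= 1
  shallow <- ipath_score(q, S, X, t = 20, psi = 2, seed = 3)
  expect_lte(shallow$raw, 1 + 1e-12)
  expect_gte(shallow$raw, 0)
})

test_that("SiNNE scores are coverage fractions with the documented guards", {
  set.seed(81)
  X <- matrix(rnorm(120), 60, 2)
  models <- sinne_fit(c(1L, 2L), X, t = 100, psi = 8, seed = 5)
  sc <- sinne_score(X[10, ], models)
  expect_equal(sc$orientation, "higher_is_outlying")
  expect_gte(sc$raw, 0); expect_lte(sc$raw, 1)
  # score granularity: t * score is an integer count of non-covering models
  expect_equal(sc$raw * 100, round(sc$raw * 100), tolerance = 1e-9)
  # a stored center is covered by its own model
  c1 <- models$models[[1]]$centers[1, ]
  q_full <- numeric(2); q_full[models$S] <- c1
  per_model_first <- {
    D <- sqrt(colSums((c1 - t(models$models[[1]]$centers))^2))
    any(D <= models$models[[1]]$radii)
  }
  expect_true(per_model_first)
  # far query scores exactly 1
  far <- sinne_score(c(1e9, 1e9), models)
  expect_equal(far$raw, 1)
})

test_that("scorer registry seeds stochastic measures per subspace", {
  set.seed(91)
  X <- matrix(rnorm(100), 25, 4)
  cfg <- measure_config(seed = 7, ipath_t = 20, sinne_t = 20)
  for (m in c("sinne", "ipath")) {
    s1 <- oam_scorer(m, X, cfg)
    s2 <- oam_scorer(m, X, cfg)
    # same subspace, fresh scorer, different visiting order: same value
    v_a <- s1$score(c(1L, 3L), q = X[2, ])
    invisible(s1$score(2L, q = X[2, ]))
    v_b <- s2$score(c(3L, 1L), q = X[2, ])
    expect_equal(v_a$raw, v_b$raw)
  }
  # rank measure demands an in-dataset query
  sr <- oam_scorer("rank", X)
  expect_error(sr$score(1L, q = X[1, ]), "query index")
  expect_equal(sr$score(1L, q_index = 2L)$orientation, "lower_is_outlying")
})
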