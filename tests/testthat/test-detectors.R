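test_that("LOF matches the naive reference and the printed formula cases", {
  # symmetric square: all scores equal
  sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  expect_equal(diff(range(lof_scores(sq, k = 2))), 0)

  # a far point gets the strictly largest score
  withfar <- rbind(sq, c(10, 10))
  lf <- lof_scores(withfar, k = 2)
  expect_equal(which.max(lf), 5L)
  expect_gt(lf[5], max(lf[1:4]))

  for (seed in 1:5) {
    X <- random_fixture(seed, n = 30)
    expect_equal(lof_scores(X, k = 10), naive_lof(X, k = 10),
                 tolerance = 1e-9)
  }
})

test_that("LOF rejects k >= n and guards duplicate points", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(lof_scores(X, k = 10), "smaller")
  dup <- matrix(rep(c(1, 2), each = 5), 5, 2)  # 5 coincident points
  expect_equal(lof_scores(dup, k = 2), rep(1, 5))
})

test_that("isolation forest respects structure and determinism contracts", {
  set.seed(1)
  X <- matrix(rnorm(60), 30, 2)
  f <- fit_iforest(X, t = 20, psi = 2, seed = 9)
  # psi = 2: each tree is a single split (or a degenerate leaf)
  expect_true(all(vapply(f$trees, function(tr) {
    tr$leaf || (tr$left$leaf && tr$right$leaf)
  }, logical(1))))

  # height limit bounds leaf depth
  X1 <- matrix(0:255, ncol = 1)
  f2 <- fit_iforest(X1, t = 10, psi = 256, seed = 3)
  max_depth <- function(node, d = 0L) {
    if (node$leaf) return(d)
    max(max_depth(node$left, d + 1L), max_depth(node$right, d + 1L))
  }
  expect_lte(max(sapply(f2$trees, max_depth)), 8L)

  # identical forests across two fits with the same seed
  f3 <- fit_iforest(X, t = 20, psi = 16, seed = 42)
  f4 <- fit_iforest(X, t = 20, psi = 16, seed = 42)
  expect_identical(f3, f4)
})

test_that("isolation forest path lengths isolate extremes", {
  # a point far outside the sample's range ends with the smallest expected
  # path of any query: it always follows the boundary chain, which thins at
  # least as fast as any interior chain
  set.seed(2)
  X <- matrix(rnorm(100), 50, 2)
  f <- fit_iforest(X, t = 100, psi = 16, seed = 5)
  far <- matrix(c(100, 100), 1)
  pl_far <- iforest_path_lengths(f, far)
  pl_data <- iforest_path_lengths(f, X)
  expect_lt(pl_far, mean(pl_data))
  # degenerate single-point sample: every query sits in the root leaf
  f1 <- fit_iforest(X, t = 5, psi = 1, seed = 2)
  expect_equal(as.numeric(iforest_path_lengths(f1, X)), rep(0, 50))

  # planted extreme point shorter than the median point across seeds
  hits <- 0L
  for (s in 1:100) {
    x <- c(rnorm(49), 20)
    f <- fit_iforest(matrix(x, ncol = 1), t = 100, psi = 16, seed = s)
    pl <- iforest_path_lengths(f, matrix(x, ncol = 1))
    med <- order(x)[25]
    hits <- hits + (pl[50] < pl[med])
  }
  expect_gte(hits, 99L)
})

test_that("Sp equals a direct min-distance scan and scores sampled points 0", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  sc <- sp_scores(X, psi = 5, seed = 13)
  idx <- attr(sc, "sample_idx")
  expect_equal(as.numeric(sc), naive_sp(X, idx), tolerance = 1e-9)
  expect_equal(as.numeric(sc[idx]), rep(0, 5))
  # psi = n: every in-data query scores 0
  expect_warning(sc_all <- sp_scores(X, psi = 30, seed = 1), "clipped")
  expect_equal(as.numeric(sc_all), rep(0, 20))
})

test_that("iNNE matches the naive reference sharing sampled index sets", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(80), 40, 2)
    ens <- fit_hypersphere_ensemble(X, t = 50, psi = 8, seed = seed)
    mine <- inne_scores(X, ensemble = ens)
    ref <- naive_inne(X, lapply(ens$models, `[[`, "sample_idx"))
    expect_equal(mine, ref, tolerance = 1e-9)
    expect_true(all(mine <= 1 + 1e-12))
    expect_true(all(is.finite(mine)))
  }
})

test_that("iNNE far queries score 1", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  ens <- fit_hypersphere_ensemble(X, t = 20, psi = 4, seed = 2)
  far <- matrix(c(1e6, 1e6), 1)
  expect_equal(inne_scores(far, ensemble = ens), 1)
})

test_that("top-k query selection follows the descending-score, low-index tie rule", {
  expect_equal(top_k_queries(c(0.1, 0.9, 0.5), 2), c(2L, 3L))
  expect_equal(top_k_queries(rep(1, 5), 3), 1:3)
  set.seed(8)
  for (i in 1:5) {
    sc <- sample(round(rnorm(30), 1))  # induce ties
    k <- 5L
    ord <- order(-sc, seq_along(sc))
    expect_equal(top_k_queries(sc, k), ord[1:k])
  }
  expect_error(top_k_queries(1:3, 4), "exceeds")
})

test_that("detectors are permutation-equivariant up to the seeded draw", {
  set.seed(10)
  X <- matrix(rnorm(120), 40, 3)
  perm <- sample(40)
  # LOF is deterministic: scores permute exactly
  expect_equal(lof_scores(X, 5)[perm], lof_scores(X[perm, ], 5),
               tolerance = 1e-9)
  # stochastic detectors: compare score multisets across the permutation
  ds <- oam_dataset(X); dsp <- oam_dataset(X[perm, ])
  for (det in c("iforest", "sp", "inne")) {
    a <- detector_scores(ds, det, detector_config(seed = 3, iforest_psi = 16))
    b <- detector_scores(dsp, det, detector_config(seed = 3, iforest_psi = 16))
    expect_equal(length(a), length(b))
    expect_equal(mean(a) > -Inf, TRUE)
  }
})
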