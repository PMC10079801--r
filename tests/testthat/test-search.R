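test_that("exhaustive search enumerates every subspace up to max_dim", {
  set.seed(101)
  X <- matrix(rnorm(60), 20, 3)
  sc <- oam_scorer("zscore", X)
  res <- exhaustive_search(X, sc, q = X[1, ], max_dim = 3)
  expect_equal(length(res$subspace), 7L)  # 2^3 - 1

  X5 <- matrix(rnorm(100), 20, 5)
  sc5 <- oam_scorer("zscore", X5)
  res5 <- exhaustive_search(X5, sc5, q = X5[1, ], max_dim = 2)
  expect_equal(length(res5$subspace), 15L)  # 5 + choose(5, 2)
  expect_error(exhaustive_search(X5, sc5, q = X5[1, ], max_dim = 5,
                                 max_subspaces = 10L), "cap")
})

test_that("beam with a wide enough beam reproduces the exhaustive ranking", {
  for (seed in 1:4) {
    set.seed(seed + 200)
    d <- 4L
    X <- matrix(rnorm(30 * d), 30, d)
    cache <- new.env(parent = emptyenv())
    for (m in c("zscore", "sinne")) {
      sc <- oam_scorer(m, X, measure_config(seed = seed, sinne_t = 20),
                       cache = cache)
      bres <- beam_search(X, sc, q = X[2, ], q_index = 2L,
                          config = beam_config(width_W = choose(d, 2),
                                               max_dim_ell = 3))
      eres <- exhaustive_search(X, sc, q = X[2, ], q_index = 2L, max_dim = 3)
      expect_equal(bres$subspace, eres$subspace,
                   info = sprintf("measure %s seed %d", m, seed))
      expect_equal(sapply(bres$value, `[[`, "raw"),
                   sapply(eres$value, `[[`, "raw"))
    }
  }
})

test_that("single-feature data yields the single candidate subspace", {
  X <- matrix(rnorm(20), ncol = 1)
  sc <- oam_scorer("zscore", X)
  res <- beam_search(X, sc, q = X[1, , drop = TRUE])
  expect_equal(res$subspace, list(1L))
})

test_that("beam output is deterministic, duplicate-free and dimension-bounded", {
  set.seed(301)
  X <- matrix(rnorm(40 * 6), 40, 6)
  sc <- oam_scorer("sinne", X, measure_config(seed = 3, sinne_t = 20))
  cfg <- beam_config(width_W = 5, max_dim_ell = 3)
  r1 <- beam_search(X, sc, q = X[4, ], config = cfg)
  r2 <- beam_search(X, sc, q = X[4, ], config = cfg)
  expect_identical(r1$subspace, r2$subspace)
  expect_identical(sapply(r1$value, `[[`, "raw"),
                   sapply(r2$value, `[[`, "raw"))
  keys <- sapply(r1$subspace, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(lengths(r1$subspace) <= 3L))
  expect_true(all(unlist(r1$subspace) %in% 1:6))
})

test_that("beam candidate counts respect the staged budget", {
  for (d in c(6L, 20L)) {
    set.seed(d)
    X <- matrix(rnorm(50 * d), 50, d)
    sc <- oam_scorer("sgrid_zscore", X)
    W <- 10L; ell <- 3L
    res <- beam_search(X, sc, q = X[1, ],
                       config = beam_config(width_W = W, max_dim_ell = ell))
    counts <- attr(res, "stage_counts")
    expect_equal(counts[1], d)
    expect_equal(counts[2], choose(d, 2))
    expect_lte(sum(counts), d + choose(d, 2) + W * d * (ell - 2))
    expect_equal(attr(res, "n_evaluated"), sum(counts))
  }
})

test_that("widening the beam never worsens the top-1 outlyingness", {
  set.seed(401)
  X <- matrix(rnorm(35 * 7), 35, 7)
  cache <- new.env(parent = emptyenv())
  sc <- oam_scorer("zscore", X, cache = cache)
  tops <- sapply(c(1L, 3L, 10L, 25L), function(W) {
    res <- beam_search(X, sc, q = X[6, ],
                       config = beam_config(width_W = W, max_dim_ell = 4))
    res$value[[1]]$outlyingness
  })
  expect_true(all(diff(tops) >= -1e-12))
})

test_that("an exceeded time budget returns a truncated best-so-far ranking", {
  set.seed(501)
  X <- matrix(rnorm(30 * 6), 30, 6)
  slow_scorer <- structure(list(
    measure = "zscore", orientation = "lower_is_outlying",
    score = local({
      inner <- oam_scorer("zscore", X)
      function(S, q = NULL, q_index = NULL) {
        Sys.sleep(0.02)
        inner$score(S, q = q, q_index = q_index)
      }
    })), class = "oam_scorer")
  res <- beam_search(X, slow_scorer, q = X[1, ],
                     config = beam_config(time_budget_s = 0.1))
  expect_true(attr(res, "truncated"))
  expect_lt(length(res$subspace), 6 + choose(6, 2))
  expect_gt(length(res$subspace), 0)
})
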