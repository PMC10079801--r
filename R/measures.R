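# Subspace outlyingness measures: product-Gaussian KDE (density rank and
# density Z-score), smoothed-grid density with Z-score normalisation, the
# isolation-path score, and the SiNNE hypersphere coverage score. All are
# exposed behind one scorer contract (fit per subspace / score a query) with
# an explicit orientation, so measures with opposite senses rank alike.

#' Measure configuration
#'
#' Defaults: Silverman-style KDE bandwidths; sGrid block size w = 64 (a
#' bit-parallelism knob of grid implementations, recorded but not affecting
#' counts here); iPath with t = 100 trees on sub-samples of
#' psi = min(256, n); SiNNE with t = 100 models of psi = 8.
#'
#' @param kde_bandwidth_rule bandwidth rule id (only `"silverman"`).
#' @param sgrid_w sGrid block-size parameter.
#' @param ipath_t,ipath_psi iPath ensemble size and sub-sample size
#'   (`ipath_psi = NULL` means `min(256, n)`).
#' @param sinne_t,sinne_psi SiNNE ensemble size and sub-sample size.
#' @param seed root seed for the stochastic measures.
#' @return a list of class `oam_measure_config`.
#' @export
measure_config <- function(kde_bandwidth_rule = "silverman", sgrid_w = 64L,
                           ipath_t = 100L, ipath_psi = NULL,
                           sinne_t = 100L, sinne_psi = 8L, seed = 1L) {
  if (!identical(kde_bandwidth_rule, "silverman")) {
    stop("unknown bandwidth rule: ", kde_bandwidth_rule)
  }
  if (sinne_psi < 2L) stop("sinne_psi must be at least 2")
  structure(list(kde_bandwidth_rule = kde_bandwidth_rule,
                 sgrid_w = as.integer(sgrid_w),
                 ipath_t = as.integer(ipath_t),
                 ipath_psi = if (is.null(ipath_psi)) NULL else
                   as.integer(ipath_psi),
                 sinne_t = as.integer(sinne_t),
                 sinne_psi = as.integer(sinne_psi),
                 seed = as.integer(seed)),
            class = "oam_measure_config")
}

#' Per-dimension KDE bandwidths
#'
#' Silverman-style normal-reference rule `h_i = 1.06 sd_i n^(-1/5)` per
#' dimension, floored at `1e-9` times the column range (absolute `1e-12`
#' for constant columns) so constant features never produce a zero
#' bandwidth.
#'
#' @param data an [oam_dataset()] or numeric matrix.
#' @return numeric vector of d bandwidths.
#' @export
kde_bandwidths <- function(data) {
  X <- detector_matrix(data)
  n <- nrow(X)
  sds <- apply(X, 2L, stats::sd)
  if (n < 2L) sds[] <- 0
  rng <- apply(X, 2L, function(v) diff(range(v)))
  h <- 1.06 * sds * n^(-1 / 5)
  floor_h <- pmax(1e-9 * rng, 1e-12)
  low <- h < floor_h
  if (any(low)) {
    h[low] <- floor_h[low]
    warning("bandwidth floored for ", sum(low), " constant or near-constant",
            " feature(s)")
  }
  h
}

#' Product-Gaussian kernel density in a subspace
#'
#' `f_S(q) = (1 / (n (2 pi)^(m/2) prod_i h_i)) sum_x exp(-sum_i
#' (q_i - x_i)^2 / (2 h_i^2))` over the subspace dimensions `i in S`.
#' Lower density = more outlying.
#'
#' @param q numeric vector (full-space coordinates; only dimensions in `S`
#'   are used), or a matrix of such points.
#' @param S integer vector of 1-based feature indices.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param bandwidths optional d-vector of bandwidths; defaults to
#'   [kde_bandwidths()] of `data`.
#' @return numeric density value(s).
#' @export
kde_density <- function(q, S, data, bandwidths = NULL) {
  X <- detector_matrix(data)
  if (is.null(bandwidths)) bandwidths <- kde_bandwidths(X)
  S <- sort(as.integer(S))
  h <- bandwidths[S]
  if (any(h <= 0)) stop("bandwidths must be strictly positive")
  Q <- if (is.matrix(q)) q[, S, drop = FALSE] else
    matrix(q[S], nrow = 1L)
  Xs <- X[, S, drop = FALSE]
  n <- nrow(Xs)
  m <- length(S)
  E <- matrix(0, nrow(Q), n)
  for (j in seq_len(m)) {
    E <- E + outer(Q[, j], Xs[, j], "-")^2 / (2 * h[j]^2)
  }
  rowSums(exp(-E)) / (n * (2 * pi)^(m / 2) * prod(h))
}

# Densities of all dataset points in subspace S (each point against the
# full dataset, itself included).
kde_density_all <- function(X, S, bandwidths) {
  kde_density(X, S, X, bandwidths)
}

#' Density rank of an in-dataset query
#'
#' Ranks the KDE densities of all n points in subspace `S`; rank 1 is the
#' smallest density (most outlying) and ties share the minimal rank.
#'
#' @param q_index 1-based row index of the query in `data`.
#' @param S subspace indices.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param bandwidths optional bandwidth vector.
#' @return a [measure_value()] with the integer rank as `raw`
#'   (`lower_is_outlying`).
#' @export
density_rank <- function(q_index, S, data, bandwidths = NULL) {
  X <- detector_matrix(data)
  if (is.null(bandwidths)) bandwidths <- kde_bandwidths(X)
  q_index <- as.integer(q_index)
  if (q_index < 1L || q_index > nrow(X)) stop("q_index out of range")
  dens <- kde_density_all(X, S, bandwidths)
  rk <- sum(dens < dens[q_index]) + 1L  # min rank under ties
  measure_value(rk, "lower_is_outlying")
}

#' Density Z-score in a subspace
#'
#' `(f_S(q) - mu) / sigma` with `mu`, `sigma` the mean and population
#' standard deviation of the densities of all n points in `S`. A low
#' density gives a negative Z, so the orientation is `lower_is_outlying`.
#' When all densities coincide (`sigma = 0`) the Z-score is defined as 0
#' with a warning.
#'
#' @param q numeric query point (full-space coordinates).
#' @param S subspace indices.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param bandwidths optional bandwidth vector.
#' @param dens optional precomputed density vector of all points in `S`.
#' @return a [measure_value()] (`lower_is_outlying`).
#' @export
density_zscore <- function(q, S, data, bandwidths = NULL, dens = NULL) {
  X <- detector_matrix(data)
  if (nrow(X) < 2L) stop("density Z-score needs at least 2 records")
  if (is.null(bandwidths)) bandwidths <- kde_bandwidths(X)
  if (is.null(dens)) dens <- kde_density_all(X, S, bandwidths)
  fq <- kde_density(q, S, X, bandwidths)
  mu <- mean(dens)
  sigma <- sqrt(mean((dens - mu)^2))
  if (sigma == 0) {
    warning("all densities equal in subspace; Z-score set to 0")
    return(measure_value(0, "lower_is_outlying"))
  }
  measure_value((fq - mu) / sigma, "lower_is_outlying")
}

# ---- sGrid -----------------------------------------------------------------

sgrid_nbins <- function(n) max(1L, ceiling(log2(n))) + 1L

# Grid structure over the subspace: equal-width bins per dimension over the
# data range, cell counts in a dense array keyed by a flat index.
sgrid_fit <- function(X, S) {
  S <- sort(as.integer(S))
  n <- nrow(X)
  nb <- sgrid_nbins(n)
  m <- length(S)
  lo <- numeric(m); width <- numeric(m)
  cells <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    v <- X[, S[j]]
    lo[j] <- min(v)
    rng <- max(v) - lo[j]
    width[j] <- if (rng > 0) rng / nb else 1  # constant column: one wide bin
    cells[, j] <- pmin(pmax(floor((v - lo[j]) / width[j]) + 1L, 1L), nb)
  }
  flat <- as.integer((cells - 1L) %*% nb^(seq_len(m) - 1L))
  counts <- tabulate(flat + 1L, nbins = nb^m)
  list(S = S, n = n, nb = nb, lo = lo, width = width, counts = counts,
       offsets = as.matrix(expand.grid(rep(list(-1L:1L), m))))
}

sgrid_cell_of <- function(grid, Q) {
  m <- length(grid$S)
  cells <- matrix(0L, nrow(Q), m)
  for (j in seq_len(m)) {
    cells[, j] <- pmin(pmax(floor((Q[, j] - grid$lo[j]) / grid$width[j]) + 1L,
                            1L), grid$nb)  # out-of-range points clamp
  }
  cells
}

sgrid_density_from_cells <- function(grid, cells) {
  m <- length(grid$S)
  nb <- grid$nb
  count <- numeric(nrow(cells))
  # cells covered per dimension (boundary cells lose a neighbour)
  ncov <- matrix(0, nrow(cells), m)
  for (j in seq_len(m)) {
    ncov[, j] <- pmin(cells[, j] + 1L, nb) - pmax(cells[, j] - 1L, 1L) + 1L
  }
  for (r in seq_len(nrow(grid$offsets))) {
    nc <- sweep(cells, 2L, grid$offsets[r, ], "+")
    ok <- rowSums(nc >= 1L & nc <= nb) == m
    if (!any(ok)) next
    flat <- as.integer((nc[ok, , drop = FALSE] - 1L) %*% nb^(seq_len(m) - 1L))
    count[ok] <- count[ok] + grid$counts[flat + 1L]
  }
  volume <- apply(ncov, 1L, prod) * prod(grid$width)
  count / (grid$n * volume)
}

#' Smoothed-grid density in a subspace
#'
#' Each subspace dimension is partitioned into `ceiling(log2(n)) + 1`
#' equal-width bins over the data range. The smoothed count of a query is
#' the number of data points in its cell plus all cells differing by at
#' most one bin index in every subspace dimension; the density divides by n
#' and by the volume actually covered (boundary cells have fewer
#' neighbours). Points outside the data range are clamped to the boundary
#' bin. `w` is the historical block-size parameter of bit-parallel grid
#' implementations; counts are independent of it.
#'
#' @param q query point (full-space coordinates) or matrix of points.
#' @param S subspace indices.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param w block-size parameter (recorded, no effect on counts).
#' @return numeric density value(s); attribute `"count"` carries the raw
#'   smoothed count(s).
#' @export
sgrid_density <- function(q, S, data, w = 64L) {
  X <- detector_matrix(data)
  grid <- sgrid_fit(X, S)
  Q <- if (is.matrix(q)) q[, grid$S, drop = FALSE] else
    matrix(q[grid$S], nrow = 1L)
  cells <- sgrid_cell_of(grid, Q)
  dens <- sgrid_density_from_cells(grid, cells)
  vol <- rep(prod(grid$width), nrow(cells))
  for (j in seq_along(grid$S)) {
    vol <- vol * (pmin(cells[, j] + 1L, grid$nb) -
                    pmax(cells[, j] - 1L, 1L) + 1L)
  }
  attr(dens, "count") <- round(dens * grid$n * vol)
  dens
}

#' Smoothed-grid density Z-score
#'
#' The grid density is not dimensionality-unbiased, so it is normalised
#' like the KDE Z-score: `(dens(q) - mu) / sigma` over the grid densities
#' of all n points (population sigma; all-equal densities give 0 with a
#' warning). Orientation `lower_is_outlying`.
#'
#' @inheritParams sgrid_density
#' @param dens_all optional precomputed grid densities of all points.
#' @return a [measure_value()].
#' @export
sgrid_zscore <- function(q, S, data, w = 64L, dens_all = NULL) {
  X <- detector_matrix(data)
  grid <- sgrid_fit(X, S)
  if (is.null(dens_all)) {
    dens_all <- sgrid_density_from_cells(grid, sgrid_cell_of(grid, X[, grid$S, drop = FALSE]))
  }
  Q <- if (is.matrix(q)) q[, grid$S, drop = FALSE] else
    matrix(q[grid$S], nrow = 1L)
  dq <- sgrid_density_from_cells(grid, sgrid_cell_of(grid, Q))
  mu <- mean(dens_all)
  sigma <- sqrt(mean((dens_all - mu)^2))
  if (sigma == 0) {
    warning("all grid densities equal in subspace; Z-score set to 0")
    return(measure_value(0, "lower_is_outlying"))
  }
  measure_value((dq - mu) / sigma, "lower_is_outlying")
}

# ---- iPath -----------------------------------------------------------------

#' Isolation-path score in a subspace
#'
#' Mean path length of the query over `t` isolation trees built on
#' sub-samples projected onto `S`. Shorter paths mean the query is easier
#' to isolate, so the orientation is `lower_is_outlying`.
#'
#' @param q query point (full-space coordinates) or matrix of points.
#' @param S subspace indices.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param t ensemble size.
#' @param psi sub-sample size (`NULL` = `min(256, n)`).
#' @param seed seed for the projected forest.
#' @param forest optional pre-fitted projected forest (from
#'   [fit_iforest()] on `data[, S]`).
#' @return a [measure_value()]; for a matrix `q` the `raw` field is a
#'   vector.
#' @export
ipath_score <- function(q, S, data, t = 100L, psi = NULL, seed = 1L,
                        forest = NULL) {
  X <- detector_matrix(data)
  S <- sort(as.integer(S))
  if (is.null(forest)) {
    if (is.null(psi)) psi <- min(256L, nrow(X))
    forest <- fit_iforest(X[, S, drop = FALSE], t = t, psi = psi, seed = seed)
  }
  Q <- if (is.matrix(q)) q[, S, drop = FALSE] else matrix(q[S], nrow = 1L)
  pl <- iforest_path_lengths(forest, Q)
  measure_value(if (length(pl) == 1L) pl[[1L]] else pl, "lower_is_outlying")
}

# ---- SiNNE -----------------------------------------------------------------

#' Fit SiNNE hypersphere models in a subspace
#'
#' The same hypersphere construction as iNNE, built on the data projected
#' onto `S`.
#'
#' @param S subspace indices.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param t ensemble size.
#' @param psi sub-sample size per model.
#' @param seed root seed.
#' @return an `oam_hypersphere_ensemble` on the projected space; the
#'   subspace is attached as `$S`.
#' @export
sinne_fit <- function(S, data, t = 100L, psi = 8L, seed = 1L) {
  X <- detector_matrix(data)
  S <- sort(as.integer(S))
  ens <- fit_hypersphere_ensemble(X[, S, drop = FALSE], t = t, psi = psi,
                                  seed = seed)
  ens$S <- S
  ens
}

#' SiNNE coverage score
#'
#' Per model the query scores 0 when it falls inside any ball and 1
#' otherwise; a zero-radius ball (duplicate sample points) contains only
#' exact matches of its center. The final score is the mean over models, in
#' `[0, 1]`, orientation `higher_is_outlying`.
#'
#' @param q query point (full-space coordinates) or matrix of points.
#' @param models a fitted ensemble from [sinne_fit()].
#' @return a [measure_value()]; for a matrix `q` the `raw` field is a
#'   vector.
#' @export
sinne_score <- function(q, models) {
  S <- models$S
  Q <- if (is.matrix(q)) q[, S, drop = FALSE] else matrix(q[S], nrow = 1L)
  nq <- nrow(Q)
  acc <- numeric(nq)
  for (m in models$models) {
    D <- cross_dist(Q, m$centers)
    inside <- rowSums(sweep(D, 2L, m$radii, "<=")) > 0L
    acc <- acc + as.numeric(!inside)
  }
  raw <- acc / models$t
  measure_value(if (length(raw) == 1L) raw[[1L]] else raw,
                "higher_is_outlying")
}

# ---- scorer registry -------------------------------------------------------

#' Available outlying-aspect measures
#' @return character vector of measure ids accepted by [oam_scorer()].
#' @export
oam_measures <- function() c("rank", "zscore", "sgrid_zscore", "sinne", "ipath")

#' Build a subspace scorer
#'
#' Wraps one of the outlying-aspect measures behind a uniform contract: the
#' returned object has `$orientation` and a `$score(S, q, q_index)`
#' closure returning a [measure_value()] for subspace `S`. Stochastic
#' measures (iPath, SiNNE) derive their per-subspace seed from
#' `(config$seed, S)`, so a subspace scores identically whether visited by
#' beam or exhaustive search. Expensive per-subspace state (density
#' vectors, projected forests) is memoised in `cache` when one is supplied,
#' and can be shared across queries.
#'
#' @param measure one of [oam_measures()]. `"rank"` requires in-dataset
#'   queries (`q_index`); the others take any coordinate vector.
#' @param data an [oam_dataset()] or numeric matrix.
#' @param config a [measure_config()].
#' @param cache optional environment for memoising per-subspace state.
#' @return a list of class `oam_scorer` with `measure`, `orientation`,
#'   `score`.
#' @export
oam_scorer <- function(measure, data, config = measure_config(),
                       cache = NULL) {
  measure <- match.arg(measure, oam_measures())
  X <- detector_matrix(data)
  n <- nrow(X)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  memo <- function(key, make) {
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, make(), envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
  bw <- NULL
  need_bw <- function() {
    if (is.null(bw)) bw <<- memo("..bandwidths", function() kde_bandwidths(X))
    bw
  }
  score <- switch(measure,
    rank = function(S, q = NULL, q_index = NULL) {
      if (is.null(q_index)) {
        stop("the density-rank measure requires an in-dataset query index")
      }
      dens <- memo(paste0("kde:", subspace_key(S)),
                   function() kde_density_all(X, S, need_bw()))
      rk <- sum(dens < dens[q_index]) + 1L
      measure_value(rk, "lower_is_outlying")
    },
    zscore = function(S, q, q_index = NULL) {
      if (is.null(q) && !is.null(q_index)) q <- X[q_index, ]
      dens <- memo(paste0("kde:", subspace_key(S)),
                   function() kde_density_all(X, S, need_bw()))
      density_zscore(q, S, X, bandwidths = need_bw(), dens = dens)
    },
    sgrid_zscore = function(S, q, q_index = NULL) {
      if (is.null(q) && !is.null(q_index)) q <- X[q_index, ]
      st <- memo(paste0("sgrid:", subspace_key(S)), function() {
        grid <- sgrid_fit(X, S)
        dens <- sgrid_density_from_cells(
          grid, sgrid_cell_of(grid, X[, grid$S, drop = FALSE]))
        list(grid = grid, dens = dens)
      })
      sgrid_zscore(q, S, X, w = config$sgrid_w, dens_all = st$dens)
    },
    ipath = function(S, q, q_index = NULL) {
      if (is.null(q) && !is.null(q_index)) q <- X[q_index, ]
      forest <- memo(paste0("ipath:", subspace_key(S)), function() {
        psi <- if (is.null(config$ipath_psi)) min(256L, n) else
          min(config$ipath_psi, n)
        Ss <- sort(as.integer(S))
        fit_iforest(X[, Ss, drop = FALSE], t = config$ipath_t, psi = psi,
                    seed = derive_seed(config$seed, "ipath", Ss))
      })
      ipath_score(q, S, X, forest = forest)
    },
    sinne = function(S, q, q_index = NULL) {
      if (is.null(q) && !is.null(q_index)) q <- X[q_index, ]
      models <- memo(paste0("sinne:", subspace_key(S)), function() {
        Ss <- sort(as.integer(S))
        sinne_fit(Ss, X, t = config$sinne_t,
                  psi = min(config$sinne_psi, n),
                  seed = derive_seed(config$seed, "sinne", Ss))
      })
      sinne_score(q, models)
    })
  orientation <- if (measure == "sinne") "higher_is_outlying" else
    "lower_is_outlying"
  structure(list(measure = measure, orientation = orientation, score = score,
                 config = config, cache = cache),
            class = "oam_scorer")
}
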