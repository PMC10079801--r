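# Full-space anomaly detectors: LOF, isolation forest, Sp and iNNE, plus
# top-k query selection. Distances are Euclidean on raw features by default;
# set normalize = TRUE in detector_config() to min-max normalise first.

#' Detector configuration
#'
#' Defaults follow common practice for these detectors on benchmark tabular
#' data: LOF neighbourhood k = 10; isolation forest with t = 100 trees on
#' sub-samples of psi = 256; Sp with one sub-sample of psi = 20; iNNE with
#' t = 100 hypersphere sets of psi = 8. Sub-sample sizes larger than n are
#' clipped at fit time with a warning.
#'
#' @param lof_k LOF neighbourhood size.
#' @param iforest_t,iforest_psi isolation-forest ensemble size and
#'   sub-sample size.
#' @param sp_psi Sp sub-sample size.
#' @param inne_t,inne_psi iNNE ensemble size and sub-sample size.
#' @param seed root seed for all sub-sampling.
#' @param normalize min-max normalise features before distance computations.
#' @return a list of class `oam_detector_config`.
#' @export
detector_config <- function(lof_k = 10L, iforest_t = 100L, iforest_psi = 256L,
                            sp_psi = 20L, inne_t = 100L, inne_psi = 8L,
                            seed = 1L, normalize = FALSE) {
  cfg <- list(lof_k = as.integer(lof_k), iforest_t = as.integer(iforest_t),
              iforest_psi = as.integer(iforest_psi),
              sp_psi = as.integer(sp_psi), inne_t = as.integer(inne_t),
              inne_psi = as.integer(inne_psi), seed = as.integer(seed),
              normalize = isTRUE(normalize))
  nums <- cfg[c("lof_k", "iforest_t", "iforest_psi", "sp_psi", "inne_t",
                "inne_psi")]
  if (any(unlist(nums) < 1L)) stop("detector parameters must be positive")
  if (cfg$inne_psi < 2L) stop("inne_psi must be at least 2")
  class(cfg) <- "oam_detector_config"
  cfg
}

clip_psi <- function(psi, n, what) {
  if (psi > n) {
    warning(sprintf("%s sub-sample size %d clipped to n = %d", what, psi, n))
    psi <- n
  }
  as.integer(psi)
}

detector_matrix <- function(data) {
  if (inherits(data, "oam_dataset")) data$values else as.matrix(data)
}

#' Local outlier factor scores
#'
#' Classical LOF: the score of a point is the ratio of the average local
#' reachability density (lrd) of its k nearest neighbours to its own lrd,
#' with reachability distance `max(kdist(x), dist(q, x))`. The point itself
#' is excluded from its neighbour set; k-distance ties include all tied
#' neighbours. Points whose reachability sum is zero (at least k exact
#' duplicates) get lrd = +Inf and their own LOF is set to 1.
#'
#' @param data an [oam_dataset()] or numeric matrix.
#' @param k neighbourhood size (must be `< n`).
#' @return numeric vector of LOF scores; higher = more anomalous.
#' @export
lof_scores <- function(data, k = 10L) {
  X <- detector_matrix(data)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of records")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- D[i, ]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- which(di <= kd)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    reach <- pmax(kdist[nb], D[i, nb])
    s <- sum(reach)
    lrd[i] <- if (s == 0) Inf else length(nb) / s
  }
  lof <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.finite(lrd[i])) {
      lof[i] <- 1  # duplicate-point guard
    } else {
      nb <- nbrs[[i]]
      lof[i] <- sum(lrd[nb]) / (length(nb) * lrd[i])
    }
  }
  lof
}

# Expected path length of an unsuccessful BST search in a leaf of size s:
# c(s) = 2 H(s-1) - 2 (s-1)/s, H as the exact harmonic number (leaf sizes
# are bounded by the sub-sample size, so the exact sum is cheap).
path_adjustment <- function(s) {
  if (s <= 1L) return(0)
  h <- sum(1 / seq_len(s - 1L))
  2 * h - 2 * (s - 1L) / s
}

build_itree_node <- function(X, idx, depth, hlim) {
  n_node <- length(idx)
  if (n_node <= 1L || depth >= hlim) {
    return(list(leaf = TRUE, size = n_node))
  }
  sub <- X[idx, , drop = FALSE]
  lo <- apply(sub, 2L, min)
  hi <- apply(sub, 2L, max)
  splittable <- which(hi > lo)
  if (length(splittable) == 0L) {
    return(list(leaf = TRUE, size = n_node))  # all points identical
  }
  f <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
  sv <- stats::runif(1L, lo[f], hi[f])
  go_left <- X[idx, f] < sv
  list(leaf = FALSE, feature = f, split = sv, size = n_node,
       left = build_itree_node(X, idx[go_left], depth + 1L, hlim),
       right = build_itree_node(X, idx[!go_left], depth + 1L, hlim))
}

#' Fit an isolation forest
#'
#' Builds `t` isolation trees, each on a sub-sample of size `psi` drawn
#' without replacement. Splits pick a feature uniformly among those with
#' positive range and a split value uniformly inside the node's (min, max)
#' on that feature; growth stops at singleton (or all-identical) nodes or at
#' the height limit `ceiling(log2(psi))`. Per-tree seeds are derived from
#' the root seed, so the fit is reproducible and order-independent.
#'
#' @param data an [oam_dataset()] or numeric matrix.
#' @param t number of trees.
#' @param psi sub-sample size (clipped to `n` with a warning).
#' @param seed root seed.
#' @return an object of class `oam_iforest`.
#' @export
fit_iforest <- function(data, t = 100L, psi = 256L, seed = 1L) {
  X <- detector_matrix(data)
  n <- nrow(X)
  psi <- clip_psi(as.integer(psi), n, "iForest")
  if (psi < 1L) stop("psi must be positive")
  hlim <- max(1L, ceiling(log2(psi)))
  trees <- vector("list", t)
  for (i in seq_len(t)) {
    trees[[i]] <- with_rng(derive_seed(seed, "itree", i), {
      idx <- sample.int(n, psi)
      build_itree_node(X, idx, 0L, hlim)
    })
  }
  structure(list(trees = trees, psi = psi, t = as.integer(t),
                 d = ncol(X), height_limit = hlim, seed = as.integer(seed)),
            class = "oam_iforest")
}

tree_path_lengths <- function(tree, Q, adjust = TRUE) {
  out <- numeric(nrow(Q))
  rec <- function(node, rows, depth) {
    if (node$leaf) {
      out[rows] <<- depth + if (adjust) path_adjustment(node$size) else 0
      return(invisible(NULL))
    }
    go <- Q[rows, node$feature] < node$split
    if (any(go)) rec(node$left, rows[go], depth + 1L)
    if (any(!go)) rec(node$right, rows[!go], depth + 1L)
  }
  rec(tree, seq_len(nrow(Q)), 0L)
  out
}

#' Mean isolation path lengths
#'
#' Average path length of each query over the forest's trees. A traversal
#' ending in a leaf of size `s > 1` (truncated by the height limit or by
#' coincident points) adds the standard expected-path adjustment
#' `c(s) = 2 H(s - 1) - 2 (s - 1) / s` unless `adjust = FALSE`.
#'
#' @param forest an `oam_iforest` from [fit_iforest()].
#' @param data query points: an [oam_dataset()] or numeric matrix on the
#'   same feature space.
#' @param adjust apply the expected-path leaf adjustment.
#' @return numeric vector of mean path lengths (smaller = more anomalous).
#' @export
iforest_path_lengths <- function(forest, data, adjust = TRUE) {
  Q <- detector_matrix(data)
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  if (ncol(Q) != forest$d) stop("query dimension does not match forest")
  acc <- numeric(nrow(Q))
  for (tree in forest$trees) acc <- acc + tree_path_lengths(tree, Q, adjust)
  acc / forest$t
}

#' Isolation forest anomaly scores
#'
#' The negated mean path length, so that (as for all detectors here) higher
#' values mean more anomalous.
#'
#' @inheritParams iforest_path_lengths
#' @return numeric vector of anomaly scores.
#' @export
iforest_scores <- function(forest, data, adjust = TRUE) {
  -iforest_path_lengths(forest, data, adjust = adjust)
}

#' Sp nearest-neighbour sub-sample scores
#'
#' Draws one sub-sample of size `psi` without replacement and scores every
#' point by its Euclidean distance to the nearest sub-sample member. A point
#' that is itself sampled scores 0. Higher = more anomalous.
#'
#' @param data an [oam_dataset()] or numeric matrix.
#' @param psi sub-sample size (clipped to `n` with a warning).
#' @param seed seed for the sub-sample draw.
#' @return numeric vector of scores; the sampled indices are attached as
#'   attribute `"sample_idx"`.
#' @export
sp_scores <- function(data, psi = 20L, seed = 1L) {
  X <- detector_matrix(data)
  n <- nrow(X)
  psi <- clip_psi(as.integer(psi), n, "Sp")
  idx <- with_rng(derive_seed(seed, "sp"), sample.int(n, psi))
  S <- X[idx, , drop = FALSE]
  scores <- apply(cross_dist(X, S), 1L, min)
  attr(scores, "sample_idx") <- idx
  scores
}

# One hypersphere model: centers (sampled points), their radii (distance to
# nearest neighbour within the sample) and the radius of that neighbour.
fit_hypersphere_model <- function(X, psi, seed) {
  n <- nrow(X)
  idx <- with_rng(seed, sample.int(n, psi))
  C <- X[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(C))
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min)
  radii <- D[cbind(seq_len(psi), nn)]
  list(sample_idx = idx, centers = C, radii = radii,
       nn_radius = radii[nn])
}

#' Fit the iNNE / SiNNE hypersphere ensemble
#'
#' Each of `t` models samples `psi` points without replacement; each sampled
#' point becomes the center of a ball whose radius is the Euclidean distance
#' to its nearest neighbour within the same sample.
#'
#' @param data an [oam_dataset()] or numeric matrix.
#' @param t ensemble size.
#' @param psi sub-sample size per model (at least 2; clipped to `n`).
#' @param seed root seed.
#' @return an object of class `oam_hypersphere_ensemble`.
#' @export
fit_hypersphere_ensemble <- function(data, t = 100L, psi = 8L, seed = 1L) {
  X <- detector_matrix(data)
  n <- nrow(X)
  psi <- clip_psi(as.integer(psi), n, "hypersphere ensemble")
  if (psi < 2L) stop("psi must be at least 2")
  models <- lapply(seq_len(t), function(i) {
    fit_hypersphere_model(X, psi, derive_seed(seed, "ball", i))
  })
  structure(list(models = models, t = as.integer(t), psi = psi, d = ncol(X),
                 seed = as.integer(seed)),
            class = "oam_hypersphere_ensemble")
}

# Exact (non-expanded) Euclidean cross-distances; the sub-sample side is
# always small here, so the per-center loop is cheap and avoids the
# cancellation error of the squared-norm expansion.
cross_dist <- function(Q, C) {
  out <- matrix(0, nrow(Q), nrow(C))
  tQ <- t(Q)
  for (j in seq_len(nrow(C))) {
    out[, j] <- sqrt(colSums((tQ - C[j, ])^2))
  }
  out
}

#' iNNE anomaly scores
#'
#' For each model, the isolation score of a query falling in at least one
#' ball is `1 - tau(eta_cnn) / tau(cnn)`, where `cnn` is the covering ball
#' of minimum radius and `eta_cnn` its center's nearest neighbour; queries
#' covered by no ball score 1. The final score is the mean over the `t`
#' models; higher = more anomalous. Duplicate centers giving
#' `tau(cnn) = 0` contribute 0 for that model.
#'
#' @param data an [oam_dataset()] or numeric matrix of query points.
#' @param ensemble an `oam_hypersphere_ensemble` fitted on the same feature
#'   space, or `NULL` to fit one on `data`.
#' @param t,psi,seed ensemble parameters used when `ensemble` is `NULL`.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
inne_scores <- function(data, ensemble = NULL, t = 100L, psi = 8L,
                        seed = 1L) {
  Q <- detector_matrix(data)
  if (is.null(ensemble)) {
    ensemble <- fit_hypersphere_ensemble(Q, t = t, psi = psi, seed = seed)
  }
  if (ncol(Q) != ensemble$d) stop("query dimension does not match ensemble")
  nq <- nrow(Q)
  acc <- numeric(nq)
  for (m in ensemble$models) {
    D <- cross_dist(Q, m$centers)
    covered <- sweep(D, 2L, m$radii, "<=")
    iso <- rep(1, nq)
    hit <- which(rowSums(covered) > 0L)
    for (i in hit) {
      cand <- which(covered[i, ])
      cnn <- cand[which.min(m$radii[cand])]
      iso[i] <- if (m$radii[cnn] == 0) 0 else
        1 - m$nn_radius[cnn] / m$radii[cnn]
    }
    acc <- acc + iso
  }
  acc / ensemble$t
}

#' Run a named detector
#'
#' Convenience dispatcher used by the pipeline and the command-line front
#' end.
#'
#' @param data an [oam_dataset()].
#' @param detector one of `"lof"`, `"iforest"`, `"sp"`, `"inne"`.
#' @param config an [detector_config()].
#' @return numeric vector of anomaly scores (higher = more anomalous).
#' @export
detector_scores <- function(data, detector = c("iforest", "lof", "sp", "inne"),
                            config = detector_config()) {
  detector <- match.arg(detector)
  X <- if (config$normalize) minmax_normalize(data) else data
  switch(detector,
    lof = lof_scores(X, k = config$lof_k),
    iforest = {
      forest <- fit_iforest(X, t = config$iforest_t, psi = config$iforest_psi,
                            seed = derive_seed(config$seed, "iforest"))
      iforest_scores(forest, X)
    },
    sp = as.numeric(sp_scores(X, psi = config$sp_psi,
                              seed = derive_seed(config$seed, "sp"))),
    inne = inne_scores(X, t = config$inne_t, psi = config$inne_psi,
                       seed = derive_seed(config$seed, "inne"))
  )
}

#' Select the top-k anomalies as queries
#'
#' Indices of the k largest anomaly scores in descending score order; ties
#' are broken by lower row index.
#'
#' @param scores numeric vector of anomaly scores.
#' @param k number of queries (must be `<= length(scores)`).
#' @return integer vector of k row indices.
#' @export
top_k_queries <- function(scores, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds the number of records")
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(k)]
}
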