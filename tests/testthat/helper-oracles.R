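# Independent naive reference implementations used to validate the package
# against. These deliberately use plain double loops and textbook formulas,
# sharing no code with the package internals.

naive_lof <- function(X, k) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  diag(D) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    kdist[i] <- sort(D[i, ])[k]
    nbrs[[i]] <- which(D[i, ] <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in nbrs[[i]]) s <- s + max(kdist[j], D[i, j])
    lrd[i] <- if (s == 0) Inf else length(nbrs[[i]]) / s
  }
  sapply(seq_len(n), function(i) {
    if (!is.finite(lrd[i])) return(1)
    sum(lrd[nbrs[[i]]]) / (length(nbrs[[i]]) * lrd[i])
  })
}

naive_kde <- function(q, S, X, h) {
  n <- nrow(X)
  m <- length(S)
  total <- 0
  for (r in seq_len(n)) {
    e <- 0
    for (j in seq_along(S)) {
      e <- e + (q[S[j]] - X[r, S[j]])^2 / (2 * h[S[j]]^2)
    }
    total <- total + exp(-e)
  }
  total / (n * (2 * pi)^(m / 2) * prod(h[S]))
}

naive_sp <- function(X, sample_idx) {
  apply(X, 1L, function(q) {
    min(sapply(sample_idx, function(s) sqrt(sum((q - X[s, ])^2))))
  })
}

# iNNE score recomputed from the sampled index sets stored in the fitted
# ensemble (shares the sample draw, nothing else).
naive_inne <- function(X, sample_sets) {
  n <- nrow(X)
  t <- length(sample_sets)
  edist <- function(a, b) sqrt(sum((a - b)^2))
  total <- numeric(n)
  for (set in sample_sets) {
    psi <- length(set)
    radii <- numeric(psi)
    nnrad <- numeric(psi)
    nnidx <- integer(psi)
    for (a in seq_len(psi)) {
      ds <- sapply(seq_len(psi)[-a], function(b) edist(X[set[a], ], X[set[b], ]))
      radii[a] <- min(ds)
      nnidx[a] <- seq_len(psi)[-a][which.min(ds)]
    }
    nnrad <- radii[nnidx]
    for (i in seq_len(n)) {
      dq <- sapply(set, function(s) edist(X[i, ], X[s, ]))
      covering <- which(dq <= radii)
      if (length(covering) == 0L) {
        total[i] <- total[i] + 1
      } else {
        cnn <- covering[which.min(radii[covering])]
        total[i] <- total[i] +
          if (radii[cnn] == 0) 0 else 1 - nnrad[cnn] / radii[cnn]
      }
    }
  }
  total / t
}

# Smoothed grid count: cell of q plus all cells within +/-1 bin index per
# subspace dimension, by direct per-point enumeration.
naive_sgrid_count <- function(q, S, X) {
  n <- nrow(X)
  nb <- max(1L, ceiling(log2(n))) + 1L
  cell_idx <- function(v, lo, w) min(max(floor((v - lo) / w) + 1L, 1L), nb)
  lo <- sapply(S, function(j) min(X[, j]))
  w <- sapply(seq_along(S), function(j) {
    rng <- max(X[, S[j]]) - lo[j]
    if (rng > 0) rng / nb else 1
  })
  qc <- sapply(seq_along(S), function(j) cell_idx(q[S[j]], lo[j], w[j]))
  count <- 0L
  for (r in seq_len(n)) {
    xc <- sapply(seq_along(S), function(j) cell_idx(X[r, S[j]], lo[j], w[j]))
    if (all(abs(xc - qc) <= 1L)) count <- count + 1L
  }
  count
}

naive_quality <- function(q, S, X) {
  n <- nrow(X)
  total <- 0
  for (r in seq_len(n)) {
    kern <- 1
    for (j in S) {
      den <- q[j] + X[r, j]
      if (den != 0) kern <- kern - 2 * (q[j] - X[r, j])^2 / den
    }
    total <- total + kern
  }
  unname(total / n)
}

naive_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

naive_precision_at_n <- function(scores, labels, n_cut) {
  ord <- order(-scores, seq_along(scores))
  sum(labels[ord[seq_len(n_cut)]] == 1) / n_cut
}

random_fixture <- function(seed, n = NULL, d = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(10:60, 1)
  if (is.null(d)) d <- sample(2:6, 1)
  matrix(rnorm(n * d, sd = sample(c(0.5, 1, 3), 1)), n, d)
}
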