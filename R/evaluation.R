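# Ranking metrics for detectors (AUC, precision at n) and the chi-square
# kernel quality of discovered subspaces.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks: the probability that a randomly
#' chosen anomaly is ranked above a randomly chosen normal record, ties
#' counted one half. Equivalent to the trapezoidal ROC area and exact under
#' ties.
#'
#' @param scores numeric anomaly scores (higher = more anomalous).
#' @param labels 0/1 vector, 1 = anomaly; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision at n
#'
#' Fraction of true anomalies among the `n_cut` top-scored records; score
#' ties are broken by lower row index (as in [top_k_queries()]). Defaults
#' `n_cut` to the number of labelled anomalies.
#'
#' @inheritParams auc_score
#' @param n_cut size of the top list.
#' @return precision in `[0, 1]`.
#' @export
precision_at_n <- function(scores, labels, n_cut = NULL) {
  labels <- as.integer(labels)
  if (is.null(n_cut)) n_cut <- sum(labels == 1L)
  n_cut <- as.integer(n_cut)
  if (n_cut < 1L) stop("n_cut must be positive")
  if (n_cut > length(scores)) stop("n_cut exceeds the number of records")
  top <- top_k_queries(scores, n_cut)
  sum(labels[top] == 1L) / n_cut
}

#' Chi-square kernel quality of a subspace
#'
#' Mean chi-square kernel similarity between the query and all records in
#' subspace `S`: `f = (1/n) sum_x (1 - sum_{i in S} 2 (q_i - x_i)^2 /
#' (q_i + x_i))`. Lower values mean the query is further from the data in
#' `S`, i.e. a better (more outlying) explanation. The kernel requires
#' non-negative inputs, so both the query and the data must be min-max
#' normalised to `[0, 1]` (see [minmax_normalize()]); terms with
#' `q_i + x_i = 0` contribute 0.
#'
#' @param q normalised query point (full-space coordinates in `[0, 1]`).
#' @param S subspace indices.
#' @param data normalised [oam_dataset()] or matrix with values in
#'   `[0, 1]`.
#' @param tol tolerance for the normalisation check.
#' @return the quality value `f` (a plain number; lower = more outlying).
#' @export
subspace_quality <- function(q, S, data, tol = 1e-8) {
  X <- detector_matrix(data)
  S <- sort(as.integer(S))
  if (length(S) == 0L) stop("subspace must be non-empty")
  Xs <- X[, S, drop = FALSE]
  qs <- q[S]
  if (min(Xs) < -tol || max(Xs) > 1 + tol || min(qs) < -tol ||
      max(qs) > 1 + tol) {
    stop("subspace_quality requires min-max normalised inputs in [0, 1]")
  }
  acc <- numeric(nrow(Xs))
  for (j in seq_along(S)) {
    num <- (qs[j] - Xs[, j])^2
    den <- qs[j] + Xs[, j]
    term <- ifelse(den == 0, 0, 2 * num / den)
    acc <- acc + term
  }
  mean(1 - acc)
}

#' Per-measure win counts across queries
#'
#' For each query, the measure whose top-ranked subspace has the lowest
#' quality value wins; ties award every tied measure. Input is a data frame
#' with one row per (query, measure) top-1 subspace, as produced by
#' [explain_anomalies()] (`rank == 1` rows of the report).
#'
#' @param top1 data frame with columns `query`, `measure`, `quality`.
#' @param tol numeric tolerance for quality ties.
#' @return named integer vector of win counts per measure.
#' @export
compare_measures <- function(top1, tol = 1e-12) {
  need <- c("query", "measure", "quality")
  if (!all(need %in% names(top1))) {
    stop("top1 must have columns query, measure, quality")
  }
  measures <- sort(unique(top1$measure))
  per_query <- split(top1, top1$query)
  sets <- lapply(per_query, function(df) sort(unique(df$measure)))
  if (length(unique(sets)) > 1L) {
    stop("all queries must be scored by the same set of measures")
  }
  wins <- stats::setNames(integer(length(measures)), measures)
  for (df in per_query) {
    best <- min(df$quality)
    winners <- df$measure[df$quality <= best + tol]
    wins[winners] <- wins[winners] + 1L
  }
  wins
}
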