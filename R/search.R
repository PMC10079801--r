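# Subspace search: the three-stage beam search used for all measures, and
# an exhaustive enumeration used as a reference and for small problems.

#' Beam search configuration
#'
#' @param width_W beam width: number of best subspaces kept per level.
#' @param max_dim_ell maximum subspace dimensionality explored.
#' @param time_budget_s optional wall-clock budget in seconds; when
#'   exceeded the search returns its best-so-far ranking flagged as
#'   truncated.
#' @param top_m number of subspaces kept per query in reports (internal
#'   ranking is complete).
#' @return a list of class `oam_beam_config`.
#' @export
beam_config <- function(width_W = 100L, max_dim_ell = 3L,
                        time_budget_s = NULL, top_m = 10L) {
  if (width_W < 1L) stop("beam width must be at least 1")
  if (max_dim_ell < 1L) stop("max_dim_ell must be at least 1")
  structure(list(width_W = as.integer(width_W),
                 max_dim_ell = as.integer(max_dim_ell),
                 time_budget_s = time_budget_s,
                 top_m = as.integer(top_m)),
            class = "oam_beam_config")
}

# Shared ranking rule: outlyingness descending, then smaller dimension,
# then lexicographic index order.
rank_scored_subspaces <- function(subspaces, values) {
  out <- vapply(values, function(v) v$outlyingness, numeric(1L))
  dims <- lengths(subspaces)
  keys <- vapply(subspaces, subspace_sort_key, character(1L))
  ord <- order(-out, dims, keys)
  structure(list(subspace = subspaces[ord],
                 value = values[ord]),
            class = "oam_subspace_ranking")
}

#' @export
print.oam_subspace_ranking <- function(x, n = 10L, ...) {
  k <- min(n, length(x$subspace))
  cat(sprintf("subspace ranking (%d evaluated, showing %d):\n",
              length(x$subspace), k))
  for (i in seq_len(k)) {
    v <- x$value[[i]]
    cat(sprintf("  %2d. {%s}  raw = %s  outlyingness = %s\n", i,
                paste(x$subspace[[i]], collapse = ", "),
                format(v$raw, digits = 6),
                format(v$outlyingness, digits = 6)))
  }
  if (isTRUE(attr(x, "truncated"))) cat("  [truncated by time budget]\n")
  invisible(x)
}

#' Staged beam search for the most outlying subspace
#'
#' Stage 1 scores all d one-dimensional subspaces; stage 2 scores all
#' `choose(d, 2)` two-dimensional subspaces exhaustively; each further
#' stage `l = 3, ..., ell` expands only the current top-W subspaces of
#' dimension `l - 1` by every unused feature, deduplicating canonical
#' (sorted) forms. All evaluated subspaces are returned ranked by
#' outlyingness (descending), ties broken by smaller dimension then
#' lexicographic indices. The total number of evaluations is at most
#' `d + choose(d, 2) + W * d * (ell - 2)`.
#'
#' @param data an [oam_dataset()] or numeric matrix.
#' @param scorer an [oam_scorer()] built on the same data.
#' @param q query point coordinates; defaults to `data[q_index, ]`.
#' @param q_index optional in-dataset query row index (required by the
#'   density-rank measure).
#' @param config a [beam_config()].
#' @return an `oam_subspace_ranking`: parallel lists `subspace` and
#'   `value`, with attributes `"stage_counts"` (subspaces evaluated per
#'   stage) and `"truncated"`.
#' @export
beam_search <- function(data, scorer, q = NULL, q_index = NULL,
                        config = beam_config()) {
  X <- detector_matrix(data)
  d <- ncol(X)
  if (is.null(q)) {
    if (is.null(q_index)) stop("supply q or q_index")
    q <- X[q_index, ]
  }
  ell <- min(config$max_dim_ell, d)
  t0 <- Sys.time()
  over_budget <- function() {
    !is.null(config$time_budget_s) &&
      as.numeric(Sys.time() - t0, units = "secs") > config$time_budget_s
  }
  visited <- new.env(parent = emptyenv())
  subspaces <- list(); values <- list()
  truncated <- FALSE
  stage_counts <- integer(0)
  evaluate_stage <- function(cands) {
    done <- 0L
    for (S in cands) {
      if (over_budget()) { truncated <<- TRUE; break }
      key <- subspace_key(S)
      if (exists(key, envir = visited, inherits = FALSE)) next
      assign(key, TRUE, envir = visited)
      i <- length(subspaces) + 1L
      subspaces[[i]] <<- S
      values[[i]] <<- scorer$score(S, q = q, q_index = q_index)
      done <- done + 1L
    }
    done
  }
  # stage 1: all 1-D subspaces
  stage_counts <- c(stage_counts, evaluate_stage(as.list(seq_len(d))))
  # stage 2: all 2-D subspaces
  if (ell >= 2L && d >= 2L && !truncated) {
    pairs <- utils::combn(d, 2L, simplify = FALSE)
    stage_counts <- c(stage_counts, evaluate_stage(pairs))
  }
  # stages 3..ell: beam expansion of the top-W subspaces of the previous
  # dimension
  l <- 3L
  while (l <= ell && !truncated) {
    prev_dim <- l - 1L
    at_prev <- which(lengths(subspaces) == prev_dim)
    if (length(at_prev) == 0L) break
    out_prev <- vapply(values[at_prev], function(v) v$outlyingness,
                       numeric(1L))
    keys <- vapply(subspaces[at_prev], subspace_sort_key, character(1L))
    beam <- at_prev[order(-out_prev, keys)]
    beam <- beam[seq_len(min(config$width_W, length(beam)))]
    cands <- list()
    for (i in beam) {
      S <- subspaces[[i]]
      for (f in setdiff(seq_len(d), S)) {
        cands[[length(cands) + 1L]] <- sort(c(S, f))
      }
    }
    stage_counts <- c(stage_counts, evaluate_stage(cands))
    l <- l + 1L
  }
  res <- rank_scored_subspaces(subspaces, values)
  attr(res, "stage_counts") <- stage_counts
  attr(res, "truncated") <- truncated
  attr(res, "n_evaluated") <- length(subspaces)
  res
}

#' Exhaustive subspace enumeration
#'
#' Scores every subspace of dimension up to `max_dim` and ranks them with
#' the same rule as [beam_search()]. Intended as a reference for small d
#' and as the ground-truth oracle in tests.
#'
#' @inheritParams beam_search
#' @param max_dim maximum subspace dimensionality.
#' @param max_subspaces safety cap on the number of enumerated subspaces.
#' @return an `oam_subspace_ranking`.
#' @export
exhaustive_search <- function(data, scorer, q = NULL, q_index = NULL,
                              max_dim = 3L, max_subspaces = 100000L) {
  X <- detector_matrix(data)
  d <- ncol(X)
  if (is.null(q)) {
    if (is.null(q_index)) stop("supply q or q_index")
    q <- X[q_index, ]
  }
  max_dim <- min(max_dim, d)
  total <- sum(choose(d, seq_len(max_dim)))
  if (total > max_subspaces) {
    stop(sprintf("exhaustive search over %d subspaces exceeds cap %d",
                 total, max_subspaces))
  }
  subspaces <- list()
  for (m in seq_len(max_dim)) {
    subspaces <- c(subspaces, utils::combn(d, m, simplify = FALSE))
  }
  values <- lapply(subspaces, function(S) {
    scorer$score(S, q = q, q_index = q_index)
  })
  res <- rank_scored_subspaces(subspaces, values)
  attr(res, "n_evaluated") <- length(subspaces)
  attr(res, "truncated") <- FALSE
  res
}
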