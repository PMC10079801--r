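# End-to-end flow: detect anomalies, take the top-k as queries, explain
# each query with beam search under the selected measures, attach the
# chi-square quality of every reported subspace, and count per-measure
# wins.

#' Detect and explain anomalies
#'
#' Runs the configured detector (isolation forest by default), selects the
#' top-k scored records as queries, runs the staged beam search once per
#' (query, measure), and attaches to every reported subspace its
#' chi-square-kernel quality computed on the min-max normalised data
#' (lower = better explanation). The whole run is deterministic given the
#' root seed in `detector_cfg`/`measure_cfg`.
#'
#' @param data an [oam_dataset()].
#' @param detector detector id, see [detector_scores()].
#' @param measures character vector of measure ids, see [oam_measures()].
#' @param k number of queries (clipped to `n` with a warning).
#' @param detector_cfg a [detector_config()].
#' @param measure_cfg a [measure_config()].
#' @param beam_cfg a [beam_config()].
#' @param verbose print one progress line per (query, measure).
#' @return an object of class `oam_report`: list with `results` (data
#'   frame: `query`, `measure`, `rank`, `subspace` string of 1-based
#'   indices, `raw`, `outlyingness`, `quality`, `truncated`),
#'   `detector_scores`, `queries`, `wins`, and `metadata`.
#' @export
explain_anomalies <- function(data,
                              detector = "iforest",
                              measures = c("rank", "zscore", "sgrid_zscore",
                                           "sinne"),
                              k = 10L,
                              detector_cfg = detector_config(),
                              measure_cfg = measure_config(),
                              beam_cfg = beam_config(),
                              verbose = FALSE) {
  stopifnot(inherits(data, "oam_dataset"))
  measures <- match.arg(measures, oam_measures(), several.ok = TRUE)
  n <- nrow(data$values)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k > n) {
    warning("k clipped from ", k, " to n = ", n)
    k <- n
  }
  scores <- detector_scores(data, detector, detector_cfg)
  queries <- top_k_queries(scores, k)
  norm <- minmax_normalize(data)
  rows <- list()
  for (measure in measures) {
    cache <- new.env(parent = emptyenv())  # shared across queries
    scorer <- oam_scorer(measure, data, config = measure_cfg, cache = cache)
    for (qi in queries) {
      if (verbose) {
        message(sprintf("measure %s, query %d", measure, qi))
      }
      res <- beam_search(data, scorer, q_index = qi, config = beam_cfg)
      m_top <- min(beam_cfg$top_m, length(res$subspace))
      for (r in seq_len(m_top)) {
        S <- res$subspace[[r]]
        v <- res$value[[r]]
        rows[[length(rows) + 1L]] <- data.frame(
          query = qi, measure = measure, rank = r,
          subspace = paste(S, collapse = ";"),
          raw = v$raw, outlyingness = v$outlyingness,
          quality = subspace_quality(norm$values[qi, ], S, norm),
          truncated = isTRUE(attr(res, "truncated")),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  top1 <- results[results$rank == 1L, c("query", "measure", "quality")]
  wins <- compare_measures(top1)
  metadata <- list(
    dataset = data$name, n = n, d = ncol(data$values),
    detector = detector, measures = measures, k = k,
    detector_config = unclass(detector_cfg),
    measure_config = unclass(measure_cfg),
    beam_config = unclass(beam_cfg),
    truncated = any(results$truncated),
    package_version = as.character(utils::packageVersion("oamkit")))
  structure(list(results = results,
                 detector_scores = scores,
                 queries = queries,
                 wins = wins,
                 metadata = metadata),
            class = "oam_report")
}

#' @export
print.oam_report <- function(x, ...) {
  cat(sprintf("oam_report: %d queries x %d measures on '%s' (n = %d, d = %d)\n",
              length(x$queries), length(x$metadata$measures),
              x$metadata$dataset, x$metadata$n, x$metadata$d))
  cat("queries:", paste(x$queries, collapse = ", "), "\n")
  cat("win counts (lowest top-1 quality per query):\n")
  print(x$wins)
  if (isTRUE(x$metadata$truncated)) cat("note: some searches were truncated\n")
  invisible(x)
}

#' Write an explanation report to CSV
#'
#' One row per (query, rank, measure) with the subspace (1-based indices
#' separated by ";"), raw measure value, outlyingness and quality; numbers
#' are printed with 6 significant digits. Round-trips through
#' [read_report()]. Run metadata is written alongside as
#' `<path>.meta.json` when `metadata = TRUE`.
#'
#' @param report an `oam_report` from [explain_anomalies()], or its
#'   `results` data frame.
#' @param path output CSV path.
#' @param metadata also write the JSON metadata file.
#' @export
write_report <- function(report, path, metadata = TRUE) {
  df <- if (inherits(report, "oam_report")) report$results else report
  out <- df
  for (col in c("raw", "outlyingness", "quality")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.6g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (metadata && inherits(report, "oam_report")) {
    jsonlite::write_json(report$metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an explanation report written by [write_report()]
#'
#' @param path CSV path.
#' @return the report's `results` data frame.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subspace = "character"))
  df
}

#' Parse a report's subspace column into index vectors
#'
#' @param subspace character vector like `"2;5;7"`.
#' @return list of integer vectors.
#' @export
parse_subspace <- function(subspace) {
  lapply(strsplit(as.character(subspace), ";", fixed = TRUE),
         function(p) sort(as.integer(p)))
}
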