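# Internal helpers: deterministic seed derivation and RNG scoping.

#' Derive a child seed from a root seed and a key
#'
#' All stochastic components (trees, hypersphere models, per-subspace
#' scorers) draw their randomness from child seeds derived deterministically
#' from one root seed, so that every result is reproducible from a single
#' integer and independent of evaluation order.
#'
#' @param seed integer root seed.
#' @param ... character or numeric key components (e.g. "tree", 7, or a
#'   subspace index vector).
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, unlist(list(...))), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 0
  m <- 2147483629  # large prime < 2^31
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is
# untouched.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonical string key for a subspace (sorted 1-based indices).
subspace_key <- function(S) paste(sort(as.integer(S)), collapse = ",")

# Fixed-width key used only for lexicographic tie-breaking in rankings.
subspace_sort_key <- function(S) {
  paste(sprintf("%06d", sort(as.integer(S))), collapse = ",")
}

#' Construct a measure value
#'
#' Wraps a raw scoring-measure value together with its orientation and a
#' comparable outlyingness (always larger = more outlying), so measures with
#' opposite senses (density rank: lower is more outlying; SiNNE: higher is
#' more outlying) can be ranked by one rule.
#'
#' @param raw raw measure value.
#' @param orientation `"lower_is_outlying"` or `"higher_is_outlying"`.
#' @return a list with elements `raw`, `orientation`, `outlyingness`.
#' @export
measure_value <- function(raw,
                          orientation = c("higher_is_outlying",
                                          "lower_is_outlying")) {
  orientation <- match.arg(orientation)
  out <- if (orientation == "higher_is_outlying") raw else -raw
  structure(list(raw = raw, orientation = orientation, outlyingness = out),
            class = "oam_measure_value")
}

#' @export
print.oam_measure_value <- function(x, ...) {
  cat(sprintf("measure value: raw = %s (%s), outlyingness = %s\n",
              format(x$raw, digits = 6), x$orientation,
              format(x$outlyingness, digits = 6)))
  invisible(x)
}
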