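# Synthetic benchmark generator: Gaussian inlier clusters with a small
# anomaly fraction whose anomalies are extreme only inside a known planted
# subspace, plus irrelevant uniform noise features. Emulates the regimes of
# public medical anomaly benchmarks (n from tens to thousands, d up to the
# low hundreds, anomaly fractions of a few percent) without downloads.

#' Specification for a synthetic dataset with a planted outlying subspace
#'
#' Normal records are drawn from a mixture of `n_clusters` spherical
#' Gaussians (unit sigma) on the informative features and uniform noise on
#' the trailing `noise_features` columns. Each anomaly is a copy of a
#' randomly chosen normal record, displaced by `shift` (in units of the
#' cluster sigma, with a random sign per dimension) on exactly the
#' `outlying_subspace` dimensions -- so anomalies are unremarkable
#' everywhere else and subspace recovery is a sharp test.
#'
#' @param n_normals,n_anomalies record counts (`n_anomalies >= 1`).
#' @param d total number of features.
#' @param outlying_subspace planted subspace (1-based indices; must lie in
#'   the informative features, i.e. all `<= d - noise_features`).
#' @param shift displacement per planted dimension, in cluster-sigma units.
#' @param n_clusters number of Gaussian inlier clusters.
#' @param noise_features number of trailing uniform-noise features.
#' @param seed root seed.
#' @return a list of class `oam_synthetic_spec`.
#' @export
synthetic_spec <- function(n_normals = 475L, n_anomalies = 25L, d = 8L,
                           outlying_subspace = c(1L, 2L), shift = 5,
                           n_clusters = 1L, noise_features = 0L, seed = 1L) {
  spec <- list(n_normals = as.integer(n_normals),
               n_anomalies = as.integer(n_anomalies), d = as.integer(d),
               outlying_subspace = sort(as.integer(outlying_subspace)),
               shift = as.numeric(shift), n_clusters = as.integer(n_clusters),
               noise_features = as.integer(noise_features),
               seed = as.integer(seed))
  if (spec$n_anomalies < 1L) stop("need at least one anomaly")
  if (spec$n_normals < 1L) stop("need at least one normal record")
  if (spec$noise_features >= spec$d) stop("noise_features must be < d")
  if (spec$shift < 0) stop("shift must be non-negative")
  d_inf <- spec$d - spec$noise_features
  if (any(spec$outlying_subspace < 1L) ||
      any(spec$outlying_subspace > d_inf)) {
    stop("outlying_subspace must lie within the informative features ",
         "(indices 1..", d_inf, ")")
  }
  class(spec) <- "oam_synthetic_spec"
  spec
}

#' Generate a synthetic dataset with planted anomalies
#'
#' See [synthetic_spec()] for the model. Cluster centers are drawn
#' uniformly in `[0, 10]` per informative dimension; cluster sigma is 1;
#' noise features are uniform on `[0, 10]`. The generated dataset carries
#' the planted subspace as attribute `"truth_subspace"` and the anomaly
#' row indices as `"anomaly_rows"`. Deterministic given `spec$seed`.
#'
#' @param spec an [synthetic_spec()].
#' @return a labelled [oam_dataset()].
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "oam_synthetic_spec"))
  d_inf <- spec$d - spec$noise_features
  with_rng(derive_seed(spec$seed, "synthetic"), {
    centers <- matrix(stats::runif(spec$n_clusters * d_inf, 0, 10),
                      spec$n_clusters, d_inf)
    assign_cl <- sample.int(spec$n_clusters, spec$n_normals, replace = TRUE)
    normals_inf <- centers[assign_cl, , drop = FALSE] +
      matrix(stats::rnorm(spec$n_normals * d_inf), spec$n_normals, d_inf)
    normals <- cbind(normals_inf,
                     if (spec$noise_features > 0L)
                       matrix(stats::runif(spec$n_normals *
                                             spec$noise_features, 0, 10),
                              spec$n_normals, spec$noise_features))
    base <- sample.int(spec$n_normals, spec$n_anomalies, replace = TRUE)
    anomalies <- normals[base, , drop = FALSE]
    for (j in spec$outlying_subspace) {
      signs <- sample(c(-1, 1), spec$n_anomalies, replace = TRUE)
      anomalies[, j] <- anomalies[, j] + signs * spec$shift
    }
    values <- rbind(normals, anomalies)
    labels <- c(rep(0L, spec$n_normals), rep(1L, spec$n_anomalies))
    ds <- oam_dataset(values,
                      feature_names = paste0("f", seq_len(spec$d)),
                      labels = labels, name = "synthetic")
    attr(ds, "truth_subspace") <- spec$outlying_subspace
    attr(ds, "anomaly_rows") <- spec$n_normals + seq_len(spec$n_anomalies)
    ds
  })
}

#' Generate uniform data on the unit hypercube
#'
#' n i.i.d. points uniform on `[0, 1]^d`; the baseline distribution for
#' dimensionality-unbiasedness checks.
#'
#' @param n,d number of points and dimensions (`n >= 1`).
#' @param seed seed.
#' @return an unlabelled [oam_dataset()].
#' @export
generate_uniform <- function(n, d, seed = 1L) {
  n <- as.integer(n); d <- as.integer(d)
  if (n < 1L || d < 1L) stop("n and d must be at least 1")
  values <- with_rng(derive_seed(seed, "uniform"),
                     matrix(stats::runif(n * d), n, d))
  oam_dataset(values, feature_names = paste0("u", seq_len(d)),
              name = "uniform")
}
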