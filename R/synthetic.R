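#' Synthetic multi-task specification
#'
#' Describes a download-free multi-task regression benchmark with the
#' statistical structure the framework assumes: sparse binary
#' (fingerprint-like) features, cluster-structured feature covariance,
#' partially shared response coefficients and heterogeneous task sizes.
#' Cluster structure is placed in BOTH the feature distribution (so the
#' covariance distance can detect it) and the response coefficients (so
#' neighbour transfer helps) — the premise that feature-distribution
#' similarity predicts transfer utility.
#'
#' @param T Number of tasks (endpoints).
#' @param sizes Integer vector of per-task row counts (length `T`).
#' @param d Feature width.
#' @param n_clusters Number of covariance/response clusters; tasks are
#'   assigned round-robin.
#' @param relatedness rho in `[0, 1]`: task t in cluster c responds to
#'   `rho * beta_c + (1 - rho) * beta_t` with a task-private `beta_t`
#'   (1 = tasks within a cluster share coefficients exactly).
#' @param feature_sparsity Activation probability of a cluster's active
#'   feature columns, in (0, 1); inactive columns fire at 1/10 of it.
#' @param noise_sd Standard deviation of the additive Gaussian label
#'   noise.
#' @param seed Integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(T = 6L, sizes = rep(200L, T), d = 50L, n_clusters = 2L,
                       relatedness = 0.9, feature_sparsity = 0.3,
                       noise_sd = 0.5, seed = 1L) {
  T <- as.integer(T)
  if (T < 1L) stop_cffat("T must be >= 1")
  sizes <- as.integer(sizes)
  if (length(sizes) != T) stop_cffat("sizes must have length T = %d", T)
  if (any(sizes < 3L)) stop_cffat("every task needs at least 3 rows")
  if (d < 2L) stop_cffat("d must be >= 2")
  if (n_clusters < 1L || n_clusters > T) stop_cffat("n_clusters must lie in 1..T")
  if (relatedness < 0 || relatedness > 1) stop_cffat("relatedness must lie in [0, 1]")
  if (feature_sparsity <= 0 || feature_sparsity >= 1) {
    stop_cffat("feature_sparsity must lie in (0, 1)")
  }
  if (noise_sd < 0) stop_cffat("noise_sd must be nonnegative")
  structure(list(T = T, sizes = sizes, d = as.integer(d),
                 n_clusters = as.integer(n_clusters), relatedness = relatedness,
                 feature_sparsity = feature_sparsity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Sparse coefficient vector supported on a subset of the active columns.
draw_beta <- function(d, active) {
  beta <- numeric(d)
  support <- sample(active, max(3L, round(0.3 * length(active))))
  beta[support] <- stats::rnorm(length(support), 0, 1)
  beta
}

#' Generate a synthetic multi-task collection
#'
#' Per cluster c a column-activation profile `pi_c` (each feature active
#' with its own Bernoulli rate; active columns are a cluster-specific
#' random half of the features) and a sparse coefficient vector `beta_c`
#' are drawn. Task t in cluster c draws rows `X_t ~ Bernoulli(pi_c)` and
#' `y_t = X_t (rho beta_c + (1 - rho) beta_t) + N(0, sigma^2)`. The
#' collection comes pre-split 60/20/20. Bit-identical under a fixed seed.
#'
#' @param spec A [synth_spec()].
#' @return A split [multitask_collection()]; each endpoint's metadata
#'   carries its cluster as the species code.
#' @export
generate_collection <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop_cffat("spec must be a synth_spec")
  p <- spec$feature_sparsity
  collection <- with_seed(spec$seed, {
    clusters <- lapply(seq_len(spec$n_clusters), function(c) {
      active <- sort(sample.int(spec$d, ceiling(spec$d / 2)))
      rate <- rep(p / 10, spec$d)
      rate[active] <- stats::runif(length(active), 0.5, 1.5) * p
      rate <- pmin(pmax(rate, 0.005), 0.95)
      list(active = active, rate = rate, beta = draw_beta(spec$d, active))
    })
    cluster_of <- rep_len(seq_len(spec$n_clusters), spec$T)
    endpoints <- lapply(seq_len(spec$T), function(t) {
      cl <- clusters[[cluster_of[t]]]
      n <- spec$sizes[t]
      X <- matrix(as.numeric(stats::rbinom(n * spec$d, 1L, rep(cl$rate, each = n))),
                  nrow = n, ncol = spec$d)
      beta_t <- draw_beta(spec$d, cl$active)
      beta <- spec$relatedness * cl$beta + (1 - spec$relatedness) * beta_t
      y <- as.numeric(X %*% beta) + stats::rnorm(n, 0, spec$noise_sd)
      meta <- endpoint_meta(
        t,
        species_code = ((cluster_of[t] - 1L) %% 15L) + 1L,
        route_code = ((t - 1L) %% 8L) + 1L,
        toxtype_code = (((t - 1L) %/% 8L) %% 3L) + 1L
      )
      endpoint_dataset(meta, X, y)
    })
    multitask_collection(endpoints, view_name = "synthetic")
  })
  split_collection(collection, seed = derive_seed(spec$seed, "synth-split"))
}

#' Tiny fixed worked-example collection
#'
#' Two hard-coded 3-row, 2-column endpoints backing the covariance and
#' metric hand calculations: endpoint 1 holds
#' `X = rbind(c(1, 2), c(3, 4), c(5, 6))` (whose covariance matrix is
#' `[[4, 4], [4, 4]]`) and endpoint 2 an all-zero block. Immutable across
#' calls; all rows are labelled `train`.
#'
#' @return A [multitask_collection()] with `T = 2`, `d = 2`.
#' @export
worked_example <- function() {
  e1 <- endpoint_dataset(
    endpoint_meta(1L, 1L, 1L, 1L, species_name = "example-a"),
    rbind(c(1, 2), c(3, 4), c(5, 6)),
    c(1, 2, 3),
    split = rep("train", 3))
  e2 <- endpoint_dataset(
    endpoint_meta(2L, 2L, 1L, 1L, species_name = "example-b"),
    matrix(0, 3, 2),
    c(0, 0, 0),
    split = rep("train", 3))
  multitask_collection(list(e1, e2), view_name = "worked-example")
}
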