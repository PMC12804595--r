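# Shared fixtures: small configurations and collections used across the
# suite. All stochastic fixtures are built in code under fixed seeds.

reseed_cfg <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

# A light cascade configuration for fast tests.
tiny_config <- function(seed = 1L, trees = 10L, max_layers = 2L) {
  cascade_config(trees = trees, cv_folds = 3L, max_layers = max_layers, seed = seed)
}

# Nonlinear regression data the cascade can actually deepen on.
nonlinear_data <- function(n = 200L, d = 10L, seed = 1L, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- X[, 1] + X[, 2] * X[, 3] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# A tiny split synthetic collection of related tasks.
related_collection <- function(seed = 1L, T = 3L, sizes = c(60L, 120L, 120L),
                               d = 20L, rho = 0.9) {
  generate_collection(synth_spec(T = T, sizes = sizes, d = d, n_clusters = 1L,
                                 relatedness = rho, feature_sparsity = 0.3,
                                 noise_sd = 0.5, seed = seed))
}

# Records/meta/features tables for loader tests.
toy_tables <- function() {
  records <- data.frame(
    smiles = c("a", "b", "a"),
    endpoint_id = c(1L, 1L, 2L),
    value = c(0.1, 0.2, 0.3))
  meta <- data.frame(endpoint_id = 1:2, species = c(1L, 2L),
                     route = c(1L, 1L), toxtype = c(1L, 2L))
  features <- matrix(seq_len(8), nrow = 2, byrow = TRUE,
                     dimnames = list(c("a", "b"), NULL))
  list(records = records, meta = meta, features = features)
}
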