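#' Cascade forest configuration
#'
#' The default configuration mirrors the standard deep-forest regressor:
#' each layer holds 2 random-forest and 2 extra-trees units of 100 trees
#' each; layer depth grows adaptively, gated by internal cross-validation.
#'
#' @param units Character vector of unit kinds per layer, drawn from
#'   `c("rf", "et")` (random forest / extremely randomized trees).
#' @param trees Trees per forest unit.
#' @param cv_folds Folds of the internal cross-validation that both
#'   produces out-of-fold augmentation vectors and scores each layer.
#' @param max_layers Hard cap on cascade depth.
#' @param growth_tolerance A candidate layer is retained only if its
#'   internal-CV score exceeds the best retained score by more than this.
#' @param growth_metric Layer score: `"r2"` or `"neg_mse"`.
#' @param seed Integer seed; all forest, bootstrap and fold randomness is
#'   derived from it via [derive_seed()].
#' @return A `cascade_config` object.
#' @export
cascade_config <- function(units = c("rf", "rf", "et", "et"),
                           trees = 100L, cv_folds = 3L, max_layers = 20L,
                           growth_tolerance = 1e-4,
                           growth_metric = c("r2", "neg_mse"),
                           seed = 1L) {
  growth_metric <- match.arg(growth_metric)
  units <- match.arg(units, c("rf", "et"), several.ok = TRUE)
  trees <- as.integer(trees)
  cv_folds <- as.integer(cv_folds)
  max_layers <- as.integer(max_layers)
  if (length(units) < 1L) stop_cffat("at least one unit per layer")
  if (trees < 1L) stop_cffat("trees must be >= 1")
  if (cv_folds < 2L) stop_cffat("cv_folds must be >= 2")
  if (max_layers < 1L) stop_cffat("max_layers must be >= 1")
  if (growth_tolerance < 0) stop_cffat("growth_tolerance must be nonnegative")
  structure(list(units = units, trees = trees, cv_folds = cv_folds,
                 max_layers = max_layers, growth_tolerance = growth_tolerance,
                 growth_metric = growth_metric, seed = as.integer(seed)),
            class = "cascade_config")
}

# Fit one forest unit. "rf" is a bootstrap random forest; "et" is
# extremely randomized trees (no bootstrap, one random split per
# candidate feature). Both use ranger with impurity importances.
fit_forest_unit <- function(kind, X, y, trees, seed) {
  args <- list(x = X, y = y, num.trees = trees, seed = seed,
               num.threads = 1L, importance = "impurity")
  if (kind == "et") {
    args <- c(args, list(splitrule = "extratrees", num.random.splits = 1L,
                         replace = FALSE, sample.fraction = 1))
  }
  do.call(ranger::ranger, args)
}

predict_unit <- function(unit, newdata) {
  stats::predict(unit, data = newdata, num.threads = 1L)$predictions
}

layer_colnames <- function(d, U) {
  c(paste0("f", seq_len(d)), if (U > 0) paste0("aug", seq_len(U)))
}

layer_score <- function(y, pred, metric) {
  if (metric == "neg_mse") return(-mean((pred - y)^2))
  r_squared(y, pred)
}

#' Fit a cascade forest regressor
#'
#' Layer 1 is trained on the raw features; every subsequent layer is
#' trained on the raw features concatenated with the previous layer's
#' per-unit augmentation vector. During training the augmentation for a
#' row is the out-of-fold prediction from `cv_folds` cross-fitting, which
#' also yields the internal-CV score that gates growth: a candidate layer
#' is kept only if it improves the best retained score by more than
#' `growth_tolerance`, otherwise it is discarded and growth stops.
#'
#' @param X Numeric matrix `n x d` without missing values.
#' @param y Numeric response of length `n`.
#' @param config A [cascade_config()].
#' @return A `cascade_forest` model with fields `layers` (each holding the
#'   fitted units and its expected input width), `growth_trace` (retained
#'   internal-CV scores), `d`, `n_units` and `config`.
#' @export
fit_cascade_forest <- function(X, y, config = cascade_config()) {
  check_matrix(X, "X")
  y <- as.numeric(y)
  n <- nrow(X)
  d <- ncol(X)
  if (length(y) != n) stop_cffat("length(y) must equal nrow(X)")
  if (anyNA(y) || any(!is.finite(y))) stop_cffat("y contains non-finite values")
  if (n < config$cv_folds) {
    stop_cffat("n = %d is below cv_folds = %d", n, config$cv_folds)
  }
  U <- length(config$units)
  colnames(X) <- layer_colnames(d, 0L)

  degenerate <- stats::var(y) == 0
  layers <- list()
  trace <- numeric(0)
  best <- -Inf
  Z <- X

  for (l in seq_len(config$max_layers)) {
    colnames(Z) <- layer_colnames(d, ncol(Z) - d)
    units <- lapply(seq_len(U), function(u) {
      fit_forest_unit(config$units[u], Z, y, config$trees,
                      derive_seed(config$seed, "layer", l, "unit", u))
    })
    if (degenerate) {
      # A constant target is fit perfectly by any single layer; internal
      # CV cannot rank layers (total sum of squares is zero), so stop.
      layers[[l]] <- list(units = units, input_width = ncol(Z))
      trace <- NA_real_
      break
    }
    folds <- assign_folds(n, config$cv_folds, derive_seed(config$seed, "folds", l))
    oof <- matrix(NA_real_, n, U)
    for (f in seq_len(config$cv_folds)) {
      hold <- folds == f
      for (u in seq_len(U)) {
        fit <- fit_forest_unit(config$units[u], Z[!hold, , drop = FALSE], y[!hold],
                               config$trees,
                               derive_seed(config$seed, "layer", l, "unit", u, "fold", f))
        oof[hold, u] <- predict_unit(fit, Z[hold, , drop = FALSE])
      }
    }
    score <- layer_score(y, rowMeans(oof), config$growth_metric)
    if (l > 1L && score <= best + config$growth_tolerance) break  # candidate discarded
    layers[[l]] <- list(units = units, input_width = ncol(Z))
    trace <- c(trace, score)
    best <- score
    Z <- cbind(X, oof)
  }

  structure(list(layers = layers, growth_trace = trace, d = d,
                 n_units = U, config = config),
            class = "cascade_forest")
}

# Propagate X through the cascade, returning the final layer's per-unit
# prediction matrix (m x U).
propagate <- function(model, X) {
  check_matrix(X, "X")
  if (ncol(X) != model$d) {
    stop_cffat("input width %d does not match model width d = %d",
               ncol(X), model$d)
  }
  colnames(X) <- layer_colnames(model$d, 0L)
  Z <- X
  P <- NULL
  for (l in seq_along(model$layers)) {
    colnames(Z) <- layer_colnames(model$d, ncol(Z) - model$d)
    P <- vapply(model$layers[[l]]$units, predict_unit, numeric(nrow(Z)), newdata = Z)
    P <- matrix(P, nrow = nrow(Z))
    Z <- cbind(X, P)
  }
  P
}

#' Predict from a cascade forest
#'
#' The output is the arithmetic mean over the final layer's unit
#' predictions.
#'
#' @param object A fitted `cascade_forest`.
#' @param X Numeric matrix with `d` columns.
#' @param ... Unused.
#' @return Numeric vector of length `nrow(X)`.
#' @export
predict.cascade_forest <- function(object, X, ...) {
  rowMeans(propagate(object, X))
}

#' Per-unit predictions of one cascade layer
#'
#' @param model A fitted `cascade_forest`.
#' @param layer_index Layer number in `1..depth`.
#' @param X Matrix matching that layer's recorded input width
#'   (`d + U * (layer_index - 1)` columns).
#' @return Matrix `m x U`; column u is forest unit u's prediction.
#' @export
layer_predict <- function(model, layer_index, X) {
  if (!inherits(model, "cascade_forest")) stop_cffat("not a cascade_forest")
  L <- length(model$layers)
  if (layer_index < 1L || layer_index > L) {
    stop_cffat("layer_index %s out of range 1..%d", layer_index, L)
  }
  check_matrix(X, "X")
  layer <- model$layers[[layer_index]]
  if (ncol(X) != layer$input_width) {
    stop_cffat("layer %d expects input width %d, got %d",
               layer_index, layer$input_width, ncol(X))
  }
  colnames(X) <- layer_colnames(model$d, ncol(X) - model$d)
  P <- vapply(layer$units, predict_unit, numeric(nrow(X)), newdata = X)
  matrix(P, nrow = nrow(X))
}

#' Feature importance of a cascade forest
#'
#' Averages the final layer's per-unit impurity importances (each unit's
#' vector normalised to sum 1), truncates to the first `d` positions (the
#' original features, dropping augmentation columns) and renormalises.
#'
#' @param model A fitted `cascade_forest`.
#' @return Nonnegative vector of length `d` summing to 1.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "cascade_forest")) stop_cffat("not a cascade_forest")
  final <- model$layers[[length(model$layers)]]
  imps <- lapply(final$units, function(u) {
    v <- u$variable.importance
    v <- pmax(v, 0)
    if (sum(v) > 0) v / sum(v) else rep(1 / length(v), length(v))
  })
  avg <- Reduce(`+`, imps) / length(imps)
  raw <- avg[seq_len(model$d)]
  if (sum(raw) <= 0) return(rep(1 / model$d, model$d))
  unname(raw / sum(raw))
}

#' Cascade depth
#' @param model A fitted `cascade_forest`.
#' @return Number of retained layers.
#' @export
cascade_depth <- function(model) length(model$layers)
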