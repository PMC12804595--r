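#' Aggregate training data across all endpoints
#'
#' Row-wise union, in endpoint order then row order, of every endpoint's
#' training and validation rows (a multiset over measurements — compounds
#' appearing in several endpoints stay as separate rows). Test rows are
#' never included; the returned provenance table records where every
#' aggregated row came from, which the leakage audit consumes.
#'
#' @param collection A split [multitask_collection()].
#' @return List with `X` (matrix), `y`, and `provenance`
#'   (data frame `endpoint_id`, `row` of per-endpoint row indices).
#' @export
aggregate_training_data <- function(collection) {
  parts <- lapply(collection$endpoints, function(e) {
    if (is.null(e$split)) {
      stop_cffat("endpoint %d has not been split", e$meta$endpoint_id)
    }
    r <- endpoint_rows(e, c("train", "valid"))
    list(X = r$X, y = r$y,
         prov = data.frame(endpoint_id = rep(e$meta$endpoint_id, length(r$idx)),
                           row = r$idx))
  })
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y")),
       provenance = do.call(rbind, lapply(parts, `[[`, "prov")))
}

#' Fit the source-domain model
#'
#' Trains a cascade forest on the aggregated multi-endpoint data and
#' extracts its first layer as the source-domain model used for feature
#' enhancement. Under this package's seed-derivation scheme the layer-1
#' units are independent of any deeper layers, so the cascade is grown to
#' depth 1 only — the extracted units are identical to those of a fully
#' grown cascade at a fraction of the cost. Out-of-fold predictions on the
#' aggregated rows are retained for optional leakage-free enhancement.
#'
#' @param X,y Aggregated feature matrix and labels
#'   (from [aggregate_training_data()]).
#' @param config A [cascade_config()].
#' @param provenance Optional provenance table carried into the model.
#' @return A `source_model` with the `U` layer-1 forest units, expected
#'   input width `d`, out-of-fold predictions and provenance.
#' @export
fit_source_model <- function(X, y, config = cascade_config(), provenance = NULL) {
  cfg <- config
  cfg$max_layers <- 1L
  cascade <- fit_cascade_forest(X, y, cfg)
  units <- cascade$layers[[1]]$units

  # OOF source predictions for rows that trained the source, reproducing
  # the cascade's internal cross-fitting.
  n <- nrow(X)
  U <- length(config$units)
  Z <- X
  colnames(Z) <- layer_colnames(ncol(X), 0L)
  oof <- matrix(NA_real_, n, U)
  folds <- assign_folds(n, config$cv_folds, derive_seed(config$seed, "folds", 1L))
  for (f in seq_len(config$cv_folds)) {
    hold <- folds == f
    for (u in seq_len(U)) {
      fit <- fit_forest_unit(config$units[u], Z[!hold, , drop = FALSE], y[!hold],
                             config$trees,
                             derive_seed(config$seed, "layer", 1L, "unit", u, "fold", f))
      oof[hold, u] <- predict_unit(fit, Z[hold, , drop = FALSE])
    }
  }
  structure(list(units = units, d = ncol(X), n_units = U,
                 oof = oof, provenance = provenance,
                 seed = config$seed, config = config),
            class = "source_model")
}

#' Enhance features with the source-domain model
#'
#' Appends the source model's `U` unit predictions (the layer-transfer
#' augmentation vector, 4-dimensional under the default configuration) to
#' the raw features: `[X | unit predictions]`. The first `d` columns are
#' returned unchanged.
#'
#' @param source A [fit_source_model()] result.
#' @param X Matrix with `source$d` columns.
#' @return Matrix `n x (d + U)`.
#' @export
enhance_features <- function(source, X) {
  if (!inherits(source, "source_model")) stop_cffat("source must be a source_model")
  check_matrix(X, "X")
  if (ncol(X) != source$d) {
    stop_cffat("input width %d does not match source width d = %d",
               ncol(X), source$d)
  }
  Z <- X
  colnames(Z) <- layer_colnames(source$d, 0L)
  P <- vapply(source$units, predict_unit, numeric(nrow(Z)), newdata = Z)
  P <- matrix(P, nrow = nrow(Z))
  colnames(P) <- paste0("src", seq_len(ncol(P)))
  cbind(X, P)
}

#' Enhance every endpoint of a collection
#'
#' Replaces each endpoint's feature matrix (train, validation AND test
#' partitions — endpoint models consume `d + U` columns, so all rows must
#' be enhanced) by its source-enhanced version. Split labels and labels
#' `y` are untouched.
#'
#' @param source A `source_model`.
#' @param collection Collection with `d == source$d`.
#' @param use_oof If `TRUE`, rows that trained the source model receive
#'   their out-of-fold source predictions instead of in-sample ones
#'   (leakage-sensitive studies); default `FALSE`, mirroring direct
#'   layer-transfer enhancement.
#' @return The collection with `d` increased by `source$n_units`.
#' @export
enhance_collection <- function(source, collection, use_oof = FALSE) {
  if (collection$d != source$d) {
    stop_cffat("collection width %d does not match source width %d",
               collection$d, source$d)
  }
  collection$endpoints <- lapply(collection$endpoints, function(e) {
    Xe <- enhance_features(source, e$X)
    if (use_oof && !is.null(source$provenance)) {
      mine <- source$provenance$endpoint_id == e$meta$endpoint_id
      agg_rows <- source$provenance$row[mine]
      if (length(agg_rows)) {
        Xe[agg_rows, source$d + seq_len(source$n_units)] <- source$oof[mine, ]
      }
    }
    e$X <- Xe
    e
  })
  collection$d <- collection$d + source$n_units
  collection
}
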