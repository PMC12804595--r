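#' Greedy-search options
#'
#' @param patience Number of consecutive non-improving candidates
#'   tolerated before the greedy search halts (0 = stop at the first
#'   failure, the strict reading of validation-gated stopping).
#' @param min_valid_rows Endpoints with fewer validation rows skip the
#'   greedy stage (the validation score would be too noisy) and keep the
#'   baseline pool.
#' @return A `greedy_options` list.
#' @export
greedy_options <- function(patience = 0L, min_valid_rows = 5L) {
  structure(list(patience = as.integer(patience),
                 min_valid_rows = as.integer(min_valid_rows)),
            class = "greedy_options")
}

# Pool bookkeeping: a pool is a provenance data.frame (endpoint_id, row)
# over the ENHANCED collection, plus the stacked X / y it denotes.
pool_data <- function(enhanced, pool) {
  parts <- lapply(split(seq_len(nrow(pool)), pool$endpoint_id), function(ii) {
    e <- get_endpoint(enhanced, pool$endpoint_id[ii[1]])
    list(X = e$X[pool$row[ii], , drop = FALSE], y = e$y[pool$row[ii]])
  })
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE))
}

endpoint_pool <- function(enhanced, id, labels) {
  e <- get_endpoint(enhanced, id)
  r <- endpoint_rows(e, labels)
  data.frame(endpoint_id = rep(id, length(r$idx)), row = r$idx)
}

#' Greedy neighbour incorporation for one endpoint
#'
#' Implements the sample-enhancement stage: a baseline cascade is fitted
#' on the endpoint's own (enhanced) training rows and scored by R-squared
#' on its validation rows; neighbour endpoints are then tried in ascending
#' covariance-distance order, each contributing its train + validation
#' rows to the candidate pool. A candidate is accepted only if the
#' refitted cascade strictly improves the validation score; the search
#' halts after `patience + 1` consecutive failures. The R-squared
#' reference mean is the endpoint's own training-label mean, held fixed
#' across steps so scores are comparable.
#'
#' @param i Endpoint id.
#' @param enhanced A source-enhanced, split collection.
#' @param distances A `distance_matrix` over the same endpoint ids.
#' @param config A [cascade_config()]; each refit draws a fresh seed
#'   derived from `(seed, endpoint, step)`.
#' @param options A [greedy_options()].
#' @return List `model` (cascade fitted on the accepted pool) and
#'   `result` (a `greedy_search_result`: baseline score, candidate order,
#'   accepted ids, step trajectory, pool composition).
#' @export
fit_endpoint_greedy <- function(i, enhanced, distances, config = cascade_config(),
                                options = greedy_options()) {
  e <- get_endpoint(enhanced, i)
  va <- endpoint_rows(e, "valid")
  tr <- endpoint_rows(e, "train")
  if (!length(va$idx)) stop_cffat("endpoint %d: cannot score greedy steps (empty validation set)", i)
  base_mean <- mean(tr$y)

  pool <- endpoint_pool(enhanced, i, "train")
  model <- fit_cascade_forest(tr$X, tr$y,
                              reseed(config, derive_seed(config$seed, "greedy", i, 0L)))
  baseline <- r_squared(va$y, stats::predict(model, va$X), baseline_mean = base_mean)
  best <- baseline

  candidates <- rank_neighbors(distances, i)
  trajectory <- data.frame(candidate_id = integer(0), valid_score = numeric(0),
                           accepted = logical(0))
  accepted <- integer(0)
  skipped <- length(va$idx) < options$min_valid_rows

  if (!skipped) {
    fails <- 0L
    step <- 0L
    for (cand in candidates) {
      step <- step + 1L
      cand_pool <- rbind(pool, endpoint_pool(enhanced, cand, c("train", "valid")))
      dat <- pool_data(enhanced, cand_pool)
      m <- fit_cascade_forest(dat$X, dat$y,
                              reseed(config, derive_seed(config$seed, "greedy", i, step)))
      s <- r_squared(va$y, stats::predict(m, va$X), baseline_mean = base_mean)
      ok <- s > best
      trajectory <- rbind(trajectory,
                          data.frame(candidate_id = cand, valid_score = s, accepted = ok))
      if (ok) {
        pool <- cand_pool
        model <- m
        best <- s
        accepted <- c(accepted, cand)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails > options$patience) break
      }
    }
  }

  composition <- vapply(split(pool$row, pool$endpoint_id), length, integer(1))
  result <- structure(
    list(endpoint_id = i,
         baseline_valid_score = baseline,
         final_valid_score = best,
         candidate_order = candidates,
         accepted_ids = accepted,
         trajectory = trajectory,
         best_train_pool = pool,
         best_train_composition = composition,
         greedy_skipped = skipped),
    class = "greedy_search_result")
  list(model = model, result = result)
}

reseed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' Final per-endpoint retraining
#'
#' Re-includes the endpoint's own validation rows in the best training
#' pool (minimising information loss once the greedy search is decided)
#' and retrains a cascade on the union. Test rows never enter training;
#' this is asserted on every call.
#'
#' @param i Endpoint id.
#' @param best_pool Provenance data frame of the accepted pool.
#' @param enhanced The enhanced collection.
#' @param config A [cascade_config()].
#' @return List `model` (the final `cascade_forest`) and `train_pool`
#'   (provenance of every row the final model saw).
#' @export
finalize_endpoint_model <- function(i, best_pool, enhanced, config = cascade_config()) {
  pool <- rbind(best_pool, endpoint_pool(enhanced, i, "valid"))
  for (id in unique(pool$endpoint_id)) {
    e <- get_endpoint(enhanced, id)
    test_rows <- which(e$split == "test")
    hit <- intersect(pool$row[pool$endpoint_id == id], test_rows)
    if (length(hit)) {
      stop_cffat("internal bookkeeping violation: endpoint %d test rows in training pool", id)
    }
  }
  dat <- pool_data(enhanced, pool)
  model <- fit_cascade_forest(dat$X, dat$y,
                              reseed(config, derive_seed(config$seed, "final", i)))
  list(model = model, train_pool = pool)
}

#' Fit the full multi-task cascade-forest framework
#'
#' End-to-end training: (1) aggregate every endpoint's train + validation
#' rows and fit the source-domain model; (2) enhance all endpoints'
#' features with the source model's layer-transfer predictions; (3) build
#' the covariance-distance matrix between endpoints on the raw features;
#' (4) per endpoint, run the greedy neighbour search and (5) retrain on
#' the accepted pool plus the endpoint's validation rows. Deterministic
#' under `config$seed`.
#'
#' @param collection A split [multitask_collection()] (raw features).
#' @param config A [cascade_config()].
#' @param options A [greedy_options()].
#' @param use_oof_enhancement Passed to [enhance_collection()].
#' @return A `cffat_model` holding the source model, distance matrix,
#'   per-endpoint cascades, greedy search results and training-pool
#'   provenance.
#' @export
fit_cffat <- function(collection, config = cascade_config(),
                      options = greedy_options(),
                      use_oof_enhancement = FALSE) {
  for (e in collection$endpoints) {
    if (is.null(e$split)) stop_cffat("endpoint %d has not been split", e$meta$endpoint_id)
  }
  agg <- aggregate_training_data(collection)
  source <- fit_source_model(agg$X, agg$y, reseed(config, derive_seed(config$seed, "source")),
                             provenance = agg$provenance)
  distances <- build_distance_matrix(collection, use_rows = c("train", "valid"))
  enhanced <- enhance_collection(source, collection, use_oof = use_oof_enhancement)

  ids <- collection_ids(collection)
  models <- list()
  results <- list()
  pools <- list()
  for (i in ids) {
    if (length(ids) == 1L) {
      # Degenerate single-task collection: no neighbours exist; the model
      # is the baseline cascade retrained on train + validation rows.
      e <- get_endpoint(enhanced, i)
      tr <- endpoint_rows(e, "train")
      pool <- endpoint_pool(enhanced, i, "train")
      result <- structure(
        list(endpoint_id = i, baseline_valid_score = NA_real_,
             final_valid_score = NA_real_, candidate_order = integer(0),
             accepted_ids = integer(0),
             trajectory = data.frame(candidate_id = integer(0),
                                     valid_score = numeric(0), accepted = logical(0)),
             best_train_pool = pool,
             best_train_composition = stats::setNames(nrow(pool), i),
             greedy_skipped = TRUE),
        class = "greedy_search_result")
      fin <- finalize_endpoint_model(i, pool, enhanced, config)
    } else {
      g <- tryCatch(
        fit_endpoint_greedy(i, enhanced, distances, config, options),
        error = function(err) stop_cffat("endpoint %d: %s", i, conditionMessage(err)))
      result <- g$result
      fin <- finalize_endpoint_model(i, result$best_train_pool, enhanced, config)
    }
    models[[as.character(i)]] <- fin$model
    pools[[as.character(i)]] <- fin$train_pool
    results[[as.character(i)]] <- result
  }

  structure(list(source = source, distances = distances,
                 endpoint_models = models, greedy_results = results,
                 train_pools = pools, endpoint_ids = ids,
                 d_raw = source$d, d_enhanced = source$d + source$n_units,
                 config = config, options = options, seed = config$seed),
            class = "cffat_model")
}

#' Predict one endpoint with a fitted framework
#'
#' Raw-width inputs are first enhanced through the source model, then
#' passed to the endpoint's cascade.
#'
#' @param model A `cffat_model`.
#' @param i Endpoint id.
#' @param X_raw Matrix with `model$d_raw` columns.
#' @return Numeric prediction vector of length `nrow(X_raw)`.
#' @export
predict_cffat <- function(model, i, X_raw) {
  if (!inherits(model, "cffat_model")) stop_cffat("not a cffat_model")
  key <- as.character(i)
  if (!key %in% names(model$endpoint_models)) stop_cffat("unknown endpoint %s", i)
  stats::predict(model$endpoint_models[[key]], enhance_features(model$source, X_raw))
}

#' Evaluate a fitted framework on held-out test rows
#'
#' Scores every endpoint on its test partition and averages without
#' weighting across endpoints (the framework-level performance measure
#' `P_avg`). R-squared uses the endpoint's training-split label mean as
#' reference.
#'
#' @param model A `cffat_model`.
#' @param collection The raw split collection the model was trained on
#'   (or any collection with the same endpoints and raw width).
#' @param metric `"r2"` or `"rmse"`.
#' @return List `per_endpoint` (data frame endpoint_id, n_test, r2, rmse)
#'   and `P_avg` (unweighted mean of `metric` over scored endpoints).
#' @export
evaluate_cffat <- function(model, collection, metric = c("r2", "rmse")) {
  metric <- match.arg(metric)
  rows <- list()
  for (e in collection$endpoints) {
    id <- e$meta$endpoint_id
    te <- endpoint_rows(e, "test")
    if (!length(te$idx)) {
      warning(sprintf("endpoint %d has no test rows; excluded from P_avg", id))
      next
    }
    tr <- endpoint_rows(e, "train")
    pred <- predict_cffat(model, id, te$X)
    rows[[length(rows) + 1L]] <- data.frame(
      endpoint_id = id, n_test = length(te$idx),
      r2 = r_squared(te$y, pred, baseline_mean = mean(tr$y)),
      rmse = rmse(te$y, pred))
  }
  if (!length(rows)) stop_cffat("no endpoint had test rows")
  per <- do.call(rbind, rows)
  list(per_endpoint = per, P_avg = mean(per[[metric]]))
}

#' Audit a fitted framework for train/test leakage
#'
#' Verifies that no endpoint's test rows appear in the source-model
#' aggregate or in any endpoint's final training pool.
#'
#' @param model A `cffat_model`.
#' @param collection The split collection used for fitting.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
leakage_audit <- function(model, collection) {
  test_keys <- unlist(lapply(collection$endpoints, function(e) {
    idx <- which(e$split == "test")
    paste(e$meta$endpoint_id, idx, sep = ":")
  }))
  pool_keys <- unlist(lapply(model$train_pools, function(p) {
    paste(p$endpoint_id, p$row, sep = ":")
  }))
  src_keys <- if (!is.null(model$source$provenance)) {
    paste(model$source$provenance$endpoint_id, model$source$provenance$row, sep = ":")
  } else character(0)
  hit <- intersect(test_keys, c(pool_keys, src_keys))
  if (length(hit)) {
    stop_cffat("leakage detected: %d test row(s) found in training pools", length(hit))
  }
  invisible(TRUE)
}

#' @export
print.cffat_model <- function(x, ...) {
  acc <- vapply(x$greedy_results, function(r) length(r$accepted_ids), integer(1))
  cat(sprintf("cffat_model: %d endpoints, raw width %d (enhanced %d)\n",
              length(x$endpoint_ids), x$d_raw, x$d_enhanced))
  cat(sprintf("  accepted neighbours per endpoint: %s\n", paste(acc, collapse = ", ")))
  invisible(x)
}
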