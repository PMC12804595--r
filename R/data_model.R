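#' Endpoint metadata
#'
#' A toxicity endpoint is the (species, administration route, toxicity type)
#' triple that defines one regression task. Codes follow the acute-toxicity
#' data dialect: 15 species, 8 administration modes, 3 toxicity types
#' (e.g. LD50 / LDLo / TDLo). The triple also doubles as the endpoint's
#' prior-knowledge vector (x, y, z).
#'
#' @param endpoint_id Positive integer index of the endpoint.
#' @param species_code Integer in 1..15.
#' @param route_code Integer in 1..8.
#' @param toxtype_code Integer in 1..3.
#' @param species_name,route_name,toxtype_name Optional display strings.
#' @return An `endpoint_meta` object.
#' @export
endpoint_meta <- function(endpoint_id, species_code, route_code, toxtype_code,
                          species_name = NA_character_,
                          route_name = NA_character_,
                          toxtype_name = NA_character_) {
  endpoint_id <- as.integer(endpoint_id)
  species_code <- as.integer(species_code)
  route_code <- as.integer(route_code)
  toxtype_code <- as.integer(toxtype_code)
  if (is.na(endpoint_id) || endpoint_id < 1L) {
    stop_cffat("endpoint_id must be a positive integer")
  }
  if (is.na(species_code) || species_code < 1L || species_code > 15L) {
    stop_cffat("species_code must lie in 1..15 (got %s)", species_code)
  }
  if (is.na(route_code) || route_code < 1L || route_code > 8L) {
    stop_cffat("route_code must lie in 1..8 (got %s)", route_code)
  }
  if (is.na(toxtype_code) || toxtype_code < 1L || toxtype_code > 3L) {
    stop_cffat("toxtype_code must lie in 1..3 (got %s)", toxtype_code)
  }
  structure(
    list(endpoint_id = endpoint_id, species_code = species_code,
         route_code = route_code, toxtype_code = toxtype_code,
         species_name = species_name, route_name = route_name,
         toxtype_name = toxtype_name),
    class = "endpoint_meta"
  )
}

#' One toxicity endpoint dataset
#'
#' Couples a feature matrix `X` (n x d), a continuous label vector `y`
#' (toxicity strength) and an optional per-row split assignment.
#'
#' @param meta An [endpoint_meta()].
#' @param X Numeric matrix, one row per measured compound.
#' @param y Numeric vector, `length(y) == nrow(X)`.
#' @param split Optional character vector over
#'   `c("train", "valid", "test")`, one label per row.
#' @return An `endpoint_dataset` object.
#' @export
endpoint_dataset <- function(meta, X, y, split = NULL) {
  if (!inherits(meta, "endpoint_meta")) stop_cffat("meta must be an endpoint_meta")
  check_matrix(X, "X")
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop_cffat("endpoint %d: nrow(X) = %d but length(y) = %d",
               meta$endpoint_id, nrow(X), length(y))
  }
  if (nrow(X) < 1L) stop_cffat("endpoint %d: needs at least one row", meta$endpoint_id)
  if (anyNA(y) || any(!is.finite(y))) {
    stop_cffat("endpoint %d: y contains non-finite values", meta$endpoint_id)
  }
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != nrow(X)) {
      stop_cffat("endpoint %d: split length does not match rows", meta$endpoint_id)
    }
    bad <- setdiff(unique(split), c("train", "valid", "test"))
    if (length(bad)) {
      stop_cffat("endpoint %d: unknown split label(s): %s",
                 meta$endpoint_id, paste(bad, collapse = ", "))
    }
  }
  structure(list(meta = meta, X = X, y = y, split = split),
            class = "endpoint_dataset")
}

#' Multi-task collection of toxicity endpoints
#'
#' An ordered list of [endpoint_dataset()]s sharing one feature space of
#' width `d` (one view, e.g. Avalon).
#'
#' @param endpoints List of `endpoint_dataset` objects.
#' @param view_name Name of the feature view.
#' @return A `multitask_collection` with fields `endpoints`, `d`,
#'   `view_name`, `T` (task count).
#' @export
multitask_collection <- function(endpoints, view_name = "features") {
  if (!length(endpoints)) stop_cffat("no endpoints")
  ok <- vapply(endpoints, inherits, logical(1), "endpoint_dataset")
  if (!all(ok)) stop_cffat("all elements must be endpoint_dataset objects")
  widths <- vapply(endpoints, function(e) ncol(e$X), integer(1))
  if (length(unique(widths)) != 1L) {
    stop_cffat("endpoints disagree on feature width: %s",
               paste(unique(widths), collapse = ", "))
  }
  ids <- vapply(endpoints, function(e) e$meta$endpoint_id, integer(1))
  if (anyDuplicated(ids)) stop_cffat("duplicate endpoint ids")
  structure(list(endpoints = endpoints, d = widths[[1]],
                 view_name = view_name, T = length(endpoints)),
            class = "multitask_collection")
}

#' @export
print.multitask_collection <- function(x, ...) {
  sizes <- vapply(x$endpoints, function(e) nrow(e$X), integer(1))
  cat(sprintf("multitask_collection: %d endpoints, d = %d, view = %s\n",
              x$T, x$d, x$view_name))
  cat(sprintf("  endpoint sizes: %s\n", paste(sizes, collapse = ", ")))
  invisible(x)
}

collection_ids <- function(collection) {
  vapply(collection$endpoints, function(e) e$meta$endpoint_id, integer(1))
}

get_endpoint <- function(collection, endpoint_id) {
  ids <- collection_ids(collection)
  k <- match(endpoint_id, ids)
  if (is.na(k)) stop_cffat("unknown endpoint id %s", endpoint_id)
  collection$endpoints[[k]]
}

#' Assemble a collection from record and metadata tables
#'
#' The record table carries one measurement per row with columns
#' `smiles` (or any compound key), `endpoint_id` and `value`; the metadata
#' table carries `endpoint_id,species,route,toxtype`. Features are supplied
#' as a numeric matrix whose rownames are the compound keys, or as a
#' [view_spec()] in which case the keys are treated as SMILES and routed
#' through [featurize_table()]. Duplicate compound-endpoint measurements are
#' kept as distinct rows; deduplication is left to the caller.
#'
#' @param records Data frame with columns `smiles`, `endpoint_id`, `value`.
#' @param meta Data frame with columns `endpoint_id`, `species`, `route`,
#'   `toxtype` (integer codes) and optional `*_name` columns.
#' @param features Numeric matrix with compound keys as rownames, or a
#'   `view_spec`.
#' @param view_name Stored view label when `features` is a matrix.
#' @return A [multitask_collection()].
#' @export
load_collection <- function(records, meta, features, view_name = "features") {
  records <- as.data.frame(records)
  meta <- as.data.frame(meta)
  need <- c("smiles", "endpoint_id", "value")
  if (!all(need %in% names(records))) {
    stop_cffat("records must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0L) stop_cffat("no endpoints: records table is empty")
  if (!all(c("endpoint_id", "species", "route", "toxtype") %in% names(meta))) {
    stop_cffat("meta must have columns endpoint_id, species, route, toxtype")
  }

  if (inherits(features, "view_spec")) {
    keys <- unique(records$smiles)
    F <- featurize_table(keys, features)
    rownames(F) <- keys
    view_name <- features$name
    features <- F
  }
  if (!is.matrix(features) || is.null(rownames(features))) {
    stop_cffat("features must be a matrix with compound keys as rownames")
  }
  missing_keys <- setdiff(unique(records$smiles), rownames(features))
  if (length(missing_keys)) {
    stop_cffat("no feature vector for compound key(s): %s",
               paste(utils::head(missing_keys, 5), collapse = ", "))
  }
  unknown <- setdiff(unique(records$endpoint_id), meta$endpoint_id)
  if (length(unknown)) {
    stop_cffat("unknown endpoint_id in records: %s",
               paste(unknown, collapse = ", "))
  }

  ids <- unique(records$endpoint_id)
  endpoints <- lapply(ids, function(id) {
    rows <- records[records$endpoint_id == id, , drop = FALSE]
    m <- meta[match(id, meta$endpoint_id), ]
    em <- endpoint_meta(
      id, m$species, m$route, m$toxtype,
      species_name = if ("species_name" %in% names(m)) m$species_name else NA_character_,
      route_name = if ("route_name" %in% names(m)) m$route_name else NA_character_,
      toxtype_name = if ("toxtype_name" %in% names(m)) m$toxtype_name else NA_character_
    )
    X <- features[rows$smiles, , drop = FALSE]
    rownames(X) <- NULL
    endpoint_dataset(em, X, rows$value)
  })
  multitask_collection(endpoints, view_name = view_name)
}

#' Split an endpoint into train / validation / test sets
#'
#' Rows are assigned by a uniform random permutation under `seed`. Block
#' sizes are floor-rounded from the proportions, with the remainder given
#' to the training set so that tiny endpoints stay trainable. The default
#' proportions are 60% / 20% / 20%.
#'
#' @param ds An [endpoint_dataset()].
#' @param proportions Length-3 numeric summing to 1 (train, valid, test).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return The dataset with its `split` field populated.
#' @export
split_endpoint <- function(ds, proportions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (!inherits(ds, "endpoint_dataset")) stop_cffat("ds must be an endpoint_dataset")
  if (length(proportions) != 3L || abs(sum(proportions) - 1) > 1e-8) {
    stop_cffat("proportions must be three numbers summing to 1")
  }
  n <- nrow(ds$X)
  if (n < 3L) {
    stop_cffat("endpoint %d too small to split (n = %d < 3)",
               ds$meta$endpoint_id, n)
  }
  n_valid <- floor(proportions[2] * n)
  n_test <- floor(proportions[3] * n)
  n_train <- n - n_valid - n_test
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_valid)]] <- "valid"
  split[perm[n_train + n_valid + seq_len(n_test)]] <- "test"
  ds$split <- split
  ds
}

#' Split every endpoint of a collection
#'
#' Applies [split_endpoint()] with a per-endpoint seed derived from the
#' collection seed via [derive_seed()].
#'
#' @inheritParams split_endpoint
#' @param collection A [multitask_collection()].
#' @return The collection with all endpoints split.
#' @export
split_collection <- function(collection, proportions = c(0.6, 0.2, 0.2), seed = 1L) {
  collection$endpoints <- lapply(collection$endpoints, function(e) {
    split_endpoint(e, proportions, derive_seed(seed, "split", e$meta$endpoint_id))
  })
  collection
}

# Row selector by split label(s); returns list(X, y, idx).
endpoint_rows <- function(ds, labels) {
  if (is.null(ds$split)) {
    stop_cffat("endpoint %d has not been split", ds$meta$endpoint_id)
  }
  idx <- which(ds$split %in% labels)
  list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx], idx = idx)
}

MODEL_FORMAT <- "cffat-model"
MODEL_VERSION <- 1L

#' Save / load fitted framework objects
#'
#' Persists any fitted object of this package (cascade forest, source
#' model, full framework model, collections) to a single versioned archive.
#' A round trip restores an object whose predictions are identical to the
#' original's.
#'
#' @param object The object to persist.
#' @param path File path of the archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored object.
#' @export
save_model <- function(object, path) {
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION, object = object),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_cffat("model archive not found: %s", path)
  wrapped <- tryCatch(readRDS(path),
                      error = function(e) stop_cffat("corrupt model archive: %s", path))
  if (!is.list(wrapped) || !identical(wrapped$format, MODEL_FORMAT)) {
    stop_cffat("file is not a cffat model archive: %s", path)
  }
  if (!identical(wrapped$version, MODEL_VERSION)) {
    stop_cffat("incompatible model archive version %s (expected %s)",
               wrapped$version, MODEL_VERSION)
  }
  wrapped$object
}
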