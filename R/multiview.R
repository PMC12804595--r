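#' Validate a multi-view set of collections
#'
#' A view set is a named list of [multitask_collection()]s describing the
#' same compounds, endpoints, labels and splits in different chemical
#' spaces; only the feature width may differ between views.
#'
#' @param viewset Named list of collections.
#' @return The viewset, invisibly, after validation.
#' @export
validate_viewset <- function(viewset) {
  if (!length(viewset) || is.null(names(viewset)) || any(!nzchar(names(viewset)))) {
    stop_cffat("viewset must be a non-empty named list")
  }
  ref <- viewset[[1]]
  ref_ids <- collection_ids(ref)
  for (v in names(viewset)[-1]) {
    cur <- viewset[[v]]
    if (!identical(collection_ids(cur), ref_ids)) {
      stop_cffat("view %s disagrees on endpoint ids", v)
    }
    for (k in seq_along(ref$endpoints)) {
      a <- ref$endpoints[[k]]
      b <- cur$endpoints[[k]]
      if (nrow(a$X) != nrow(b$X)) {
        stop_cffat("view %s, endpoint %d: row count mismatch", v, a$meta$endpoint_id)
      }
      if (!isTRUE(all.equal(a$y, b$y))) {
        stop_cffat("view %s, endpoint %d: labels differ", v, a$meta$endpoint_id)
      }
      if (!identical(a$split, b$split)) {
        stop_cffat("view %s, endpoint %d: split labels differ", v, a$meta$endpoint_id)
      }
    }
  }
  invisible(viewset)
}

#' Concatenate views into a single wide collection
#'
#' Per-row horizontal concatenation of the feature blocks in declared
#' view order; the resulting width is the sum of the view widths. Labels
#' and splits are untouched.
#'
#' @param viewset A validated named list of collections.
#' @return A [multitask_collection()] with `d = sum(d_v)`.
#' @export
concat_views <- function(viewset) {
  validate_viewset(viewset)
  ref <- viewset[[1]]
  ref$endpoints <- lapply(seq_along(ref$endpoints), function(k) {
    e <- ref$endpoints[[k]]
    e$X <- do.call(cbind, lapply(viewset, function(col) col$endpoints[[k]]$X))
    colnames(e$X) <- NULL
    e
  })
  ref$d <- sum(vapply(viewset, `[[`, integer(1), "d"))
  ref$view_name <- paste(names(viewset), collapse = "+")
  ref
}

#' Consensus prediction over per-view models
#'
#' Unweighted mean of the per-view framework predictions for one
#' endpoint — the consensus ensemble over independently trained
#' single-view models.
#'
#' @param models Named list of `cffat_model`s, one per view.
#' @param i Endpoint id.
#' @param inputs Named list of raw feature matrices, one per view,
#'   row-aligned across views.
#' @return Numeric prediction vector.
#' @export
consensus_predict <- function(models, i, inputs) {
  if (length(models) != length(inputs)) {
    stop_cffat("view count mismatch: %d models vs %d inputs",
               length(models), length(inputs))
  }
  if (!is.null(names(models)) && !is.null(names(inputs))) {
    if (!setequal(names(models), names(inputs))) {
      stop_cffat("model and input view names differ")
    }
    inputs <- inputs[names(models)]
  }
  ns <- vapply(inputs, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop_cffat("inputs are not row-aligned")
  preds <- mapply(function(m, X) predict_cffat(m, i, X), models, inputs,
                  SIMPLIFY = TRUE)
  rowMeans(matrix(preds, nrow = ns[[1]]))
}

#' Merge endpoints by species
#'
#' Pools all endpoints of each species into a single species-level
#' endpoint (rows stacked across administration routes and toxicity
#' types; labels untouched), for species-level association analysis. The
#' merged endpoint keeps the species code and inherits route/toxicity
#' codes from its first constituent (those codes lose meaning after
#' pooling).
#'
#' @param collection A [multitask_collection()].
#' @return A collection with one endpoint per species, endpoint ids equal
#'   to the species codes.
#' @export
species_merge <- function(collection) {
  species <- vapply(collection$endpoints, function(e) e$meta$species_code, integer(1))
  groups <- split(seq_along(collection$endpoints), species)
  endpoints <- lapply(groups, function(ii) {
    first <- collection$endpoints[[ii[1]]]
    X <- do.call(rbind, lapply(ii, function(k) collection$endpoints[[k]]$X))
    y <- unlist(lapply(ii, function(k) collection$endpoints[[k]]$y), use.names = FALSE)
    splits <- lapply(ii, function(k) collection$endpoints[[k]]$split)
    split <- if (any(vapply(splits, is.null, logical(1)))) NULL else unlist(splits)
    meta <- endpoint_meta(first$meta$species_code, first$meta$species_code,
                          first$meta$route_code, first$meta$toxtype_code,
                          species_name = first$meta$species_name)
    endpoint_dataset(meta, X, y, split)
  })
  multitask_collection(unname(endpoints), view_name = collection$view_name)
}

#' Pairwise distances between feature-importance vectors
#'
#' Euclidean distances between the (raw-feature-space) importance vectors
#' of a set of entities (species or endpoints); small distances mean
#' similar feature-importance distributions, the basis of the
#' toxicity-association analysis.
#'
#' @param importance_vectors Named list (or matrix rows) of equal-length
#'   numeric vectors.
#' @return An `importance_association` with fields `E` (symmetric
#'   labelled distance matrix) and `entity_ids`.
#' @export
importance_association <- function(importance_vectors) {
  if (is.matrix(importance_vectors)) {
    V <- importance_vectors
  } else {
    lens <- vapply(importance_vectors, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop_cffat("importance vectors differ in length: %s",
                 paste(unique(lens), collapse = ", "))
    }
    V <- do.call(rbind, importance_vectors)
  }
  E <- as.matrix(stats::dist(V, method = "euclidean"))
  dimnames(E) <- list(rownames(V), rownames(V))
  structure(list(E = E, entity_ids = rownames(V)),
            class = "importance_association")
}

#' Write an importance-association matrix as labelled TSV
#'
#' @param assoc An [importance_association()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(assoc, path) {
  df <- data.frame(entity = rownames(assoc$E), assoc$E, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
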