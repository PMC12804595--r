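#' Feature covariance matrix of one endpoint
#'
#' Sample covariance between all pairs of feature columns,
#' `(i, j) -> sum_n (X[n,i] - mean_i)(X[n,j] - mean_j) / (n - 1)`,
#' including the diagonal (the per-column variances). The full `d x d`
#' matrix summarises the endpoint's feature distribution for the
#' covariance-distance task-similarity measure.
#'
#' @param X Numeric matrix with at least 2 rows.
#' @return Symmetric `d x d` matrix of class `covariance_matrix`.
#' @export
covariance_matrix <- function(X) {
  check_matrix(X, "X")
  if (nrow(X) < 2L) stop_cffat("covariance undefined for n = %d < 2", nrow(X))
  M <- stats::cov(X)
  dimnames(M) <- NULL
  structure(M, class = c("covariance_matrix", "matrix", "array"))
}

#' Covariance distance between two endpoints
#'
#' Mean absolute element-wise difference between the two endpoints'
#' feature covariance matrices (the mean runs over all `d^2` entries).
#' Smaller values indicate more similar feature distributions.
#'
#' @param Xa,Xb Numeric matrices with the same number of columns, each
#'   with at least 2 rows.
#' @return A nonnegative scalar.
#' @export
covariance_distance <- function(Xa, Xb) {
  if (ncol(Xa) != ncol(Xb)) {
    stop_cffat("feature width mismatch: %d vs %d", ncol(Xa), ncol(Xb))
  }
  mean(abs(covariance_matrix(Xa) - covariance_matrix(Xb)))
}

#' All-pairs covariance distance matrix of a collection
#'
#' Computes [covariance_distance()] between every unordered endpoint pair
#' on the selected split partitions (raw features). The result is
#' symmetric, nonnegative and has a zero diagonal.
#'
#' @param collection A [multitask_collection()].
#' @param use_rows Split labels whose rows enter the computation; default
#'   train + validation. Use all rows with
#'   `c("train", "valid", "test")`, or `NULL` for unsplit collections.
#' @return A `distance_matrix` object with fields `D` (T x T) and
#'   `endpoint_ids`.
#' @export
build_distance_matrix <- function(collection, use_rows = c("train", "valid")) {
  ids <- collection_ids(collection)
  blocks <- lapply(collection$endpoints, function(e) {
    X <- if (is.null(use_rows) || is.null(e$split)) e$X else endpoint_rows(e, use_rows)$X
    if (nrow(X) < 2L) {
      stop_cffat("endpoint %d has %d usable row(s); need >= 2 for covariance",
                 e$meta$endpoint_id, nrow(X))
    }
    X
  })
  cms <- lapply(blocks, covariance_matrix)
  T <- length(cms)
  D <- matrix(0, T, T)
  if (T > 1L) {
    for (a in seq_len(T - 1L)) {
      for (b in seq(a + 1L, T)) {
        D[a, b] <- D[b, a] <- mean(abs(cms[[a]] - cms[[b]]))
      }
    }
  }
  structure(list(D = D, endpoint_ids = ids), class = "distance_matrix")
}

#' Rank an endpoint's neighbours by covariance distance
#'
#' Returns all other endpoint ids sorted by ascending covariance distance
#' from endpoint `i` (the endpoint itself is excluded); ties break by
#' ascending endpoint id.
#'
#' @param D A `distance_matrix` from [build_distance_matrix()].
#' @param i Endpoint id to rank neighbours for.
#' @return Integer vector of `T - 1` endpoint ids.
#' @export
rank_neighbors <- function(D, i) {
  if (!inherits(D, "distance_matrix")) stop_cffat("D must be a distance_matrix")
  k <- match(i, D$endpoint_ids)
  if (is.na(k)) stop_cffat("unknown endpoint id %s", i)
  others <- setdiff(seq_along(D$endpoint_ids), k)
  ord <- others[order(D$D[k, others], D$endpoint_ids[others])]
  D$endpoint_ids[ord]
}
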