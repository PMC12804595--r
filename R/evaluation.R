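#' Root mean square error
#'
#' @param y_true,y_pred Equal-length finite numeric vectors.
#' @return `sqrt(mean((y_pred - y_true)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop_cffat("empty vectors")
  if (length(y_true) != length(y_pred)) {
    stop_cffat("length mismatch: %d vs %d", length(y_true), length(y_pred))
  }
  if (anyNA(y_true) || anyNA(y_pred) ||
      any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stop_cffat("inputs must be finite")
  }
  sqrt(mean((y_pred - y_true)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((y_pred - y_true)^2) / sum((y_true - baseline_mean)^2)`.
#' The reference mean is, by the reporting convention of this framework,
#' the mean label of the training samples; standalone calls default to
#' `mean(y_true)`. Can be negative for very poor fits; 1 for a perfect fit.
#'
#' @param y_true,y_pred Equal-length finite numeric vectors.
#' @param baseline_mean Reference mean for the total sum of squares
#'   (training-split label mean when available); defaults to
#'   `mean(y_true)`.
#' @return A finite scalar `<= 1`.
#' @export
r_squared <- function(y_true, y_pred, baseline_mean = NULL) {
  if (length(y_true) == 0L) stop_cffat("empty vectors")
  if (length(y_true) != length(y_pred)) {
    stop_cffat("length mismatch: %d vs %d", length(y_true), length(y_pred))
  }
  if (is.null(baseline_mean)) baseline_mean <- mean(y_true)
  tss <- sum((y_true - baseline_mean)^2)
  if (tss == 0) stop_cffat("degenerate target: zero total sum of squares")
  1 - sum((y_pred - y_true)^2) / tss
}

# 3:1 re-split of the non-test rows of one CV fold, reconstructing the
# 60/20/20 geometry inside each fold.
resplit_fold <- function(idx_rest, seed) {
  n <- length(idx_rest)
  n_valid <- floor(n / 4)
  perm <- with_seed(seed, sample.int(n))
  list(train = idx_rest[perm[seq_len(n - n_valid)]],
       valid = idx_rest[perm[(n - n_valid + 1):n]])
}

#' Repeated k-fold cross-validation harness
#'
#' Reproduces the reporting protocol: per run, every endpoint's rows are
#' partitioned into `folds` folds under a run-specific seed; each fold in
#' turn is the test set while the remaining rows are re-split 3:1 into
#' train:valid (recovering the 60/20/20 geometry inside the fold). The
#' trainer is fitted on the resulting collection and scored on the fold.
#'
#' @param collection A [multitask_collection()] (split labels, if any, are
#'   ignored and reassigned per fold).
#' @param runs Number of repetitions.
#' @param folds Folds per repetition.
#' @param trainer `function(collection, seed)` returning a fitted object.
#' @param predictor `function(model, endpoint_id, X)` returning
#'   predictions; defaults to [predict_cffat()].
#' @param seed Top-level seed; run/fold seeds derive from it.
#' @return List with `scores` (long data frame: run, fold, endpoint_id,
#'   n_test, r2, rmse) and `summary` (per-endpoint means over runs x folds
#'   plus the overall unweighted means `r2_avg`, `rmse_avg`).
#' @export
repeated_cv <- function(collection, runs = 10L, folds = 5L, trainer,
                        predictor = predict_cffat, seed = 1L) {
  if (runs < 1L) stop_cffat("runs must be >= 1")
  if (folds < 2L) stop_cffat("folds must be >= 2")
  ids <- collection_ids(collection)
  sizes <- vapply(collection$endpoints, function(e) nrow(e$X), integer(1))
  usable <- sizes >= folds
  for (k in which(!usable)) {
    warning(sprintf("endpoint %d has %d rows < %d folds; skipped",
                    ids[k], sizes[k], folds))
  }
  rows <- list()
  for (r in seq_len(runs)) {
    fold_of <- lapply(seq_along(ids), function(k) {
      if (!usable[k]) return(NULL)
      assign_folds(sizes[k], folds, derive_seed(seed, "cv", r, ids[k]))
    })
    for (f in seq_len(folds)) {
      work <- collection
      work$endpoints <- lapply(seq_along(ids), function(k) {
        e <- collection$endpoints[[k]]
        if (!usable[k]) return(e)
        test_idx <- which(fold_of[[k]] == f)
        rest <- setdiff(seq_len(sizes[k]), test_idx)
        rs <- resplit_fold(rest, derive_seed(seed, "cv", r, f, ids[k], "resplit"))
        split <- character(sizes[k])
        split[rs$train] <- "train"
        split[rs$valid] <- "valid"
        split[test_idx] <- "test"
        e$split <- split
        e
      })
      model <- trainer(work, derive_seed(seed, "cv", r, f, "trainer"))
      for (k in which(usable)) {
        e <- work$endpoints[[k]]
        te <- endpoint_rows(e, "test")
        tr <- endpoint_rows(e, "train")
        if (!length(te$idx)) next
        pred <- predictor(model, ids[k], te$X)
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, fold = f, endpoint_id = ids[k], n_test = length(te$idx),
          r2 = r_squared(te$y, pred, baseline_mean = mean(tr$y)),
          rmse = rmse(te$y, pred))
      }
    }
  }
  scores <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(scores, scores$endpoint_id), function(s) {
    data.frame(endpoint_id = s$endpoint_id[1], r2 = mean(s$r2), rmse = mean(s$rmse))
  }))
  rownames(summ) <- NULL
  list(scores = scores, summary = summ,
       r2_avg = mean(summ$r2), rmse_avg = mean(summ$rmse))
}
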