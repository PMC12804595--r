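test_that("aggregation unions train+valid rows in endpoint order and excludes test rows", {
  meta1 <- endpoint_meta(1, 1, 1, 1)
  meta2 <- endpoint_meta(2, 2, 1, 1)
  e1 <- endpoint_dataset(meta1, matrix(1:20, 10, 2), 1:10,
                         split = c(rep("train", 6), rep("valid", 2), rep("test", 2)))
  e2 <- endpoint_dataset(meta2, matrix(101:114, 7, 2), 1:7,
                         split = c(rep("train", 4), "valid", rep("test", 2)))
  col <- multitask_collection(list(e1, e2))
  agg <- aggregate_training_data(col)
  expect_equal(nrow(agg$X), 13L)  # (6+2) + (4+1)
  expect_equal(length(agg$y), 13L)
  # row bookkeeping: no test row index appears in the provenance
  expect_false(any(agg$provenance$endpoint_id == 1 & agg$provenance$row %in% 9:10))
  expect_false(any(agg$provenance$endpoint_id == 2 & agg$provenance$row %in% 6:7))
  # T = 1 reduces to that endpoint's train+valid block
  agg1 <- aggregate_training_data(multitask_collection(list(e1)))
  expect_equal(agg1$X, e1$X[1:8, ], ignore_attr = TRUE)

  e3 <- endpoint_dataset(meta2, matrix(1:6, 3, 2), 1:3)
  expect_error(aggregate_training_data(multitask_collection(list(e3))),
               "not been split")
})

test_that("the source model is the layer-1 unit ensemble over width-d inputs", {
  col <- related_collection(seed = 2)
  agg <- aggregate_training_data(col)
  cfg <- tiny_config(seed = 2)
  src <- fit_source_model(agg$X, agg$y, cfg, provenance = agg$provenance)
  expect_s3_class(src, "source_model")
  expect_equal(src$d, col$d)
  expect_equal(src$n_units, 4L)
  # extraction identity: unit predictions equal the cascade's layer-1 output
  cascade <- fit_cascade_forest(agg$X, agg$y, reseed_cfg(cfg, 1L))
  src_same <- fit_source_model(agg$X, agg$y, reseed_cfg(cfg, 1L))
  Xp <- col$endpoints[[1]]$X[1:10, ]
  expect_identical(enhance_features(src_same, Xp)[, col$d + 1:4],
                   layer_predict(cascade, 1L, Xp), ignore_attr = TRUE)
  # determinism
  src2 <- fit_source_model(agg$X, agg$y, cfg)
  expect_identical(enhance_features(src, Xp), enhance_features(src2, Xp))
})

test_that("feature enhancement appends exactly U columns and preserves the raw block", {
  col <- related_collection(seed = 3)
  agg <- aggregate_training_data(col)
  src <- fit_source_model(agg$X, agg$y, tiny_config(seed = 3))
  X <- col$endpoints[[2]]$X
  Z <- enhance_features(src, X)
  expect_equal(ncol(Z), ncol(X) + 4L)
  expect_identical(Z[, seq_len(ncol(X))], X, ignore_attr = TRUE)
  expect_error(enhance_features(src, X[, -1]), "width")
})

test_that("collection enhancement raises d by U and leaves labels and splits alone", {
  col <- related_collection(seed = 4)
  agg <- aggregate_training_data(col)
  src <- fit_source_model(agg$X, agg$y, tiny_config(seed = 4),
                          provenance = agg$provenance)
  enh <- enhance_collection(src, col)
  expect_equal(enh$d, col$d + 4L)
  for (k in seq_along(col$endpoints)) {
    expect_identical(enh$endpoints[[k]]$y, col$endpoints[[k]]$y)
    expect_identical(enh$endpoints[[k]]$split, col$endpoints[[k]]$split)
    expect_equal(ncol(enh$endpoints[[k]]$X), col$d + 4L)
  }
  # out-of-fold variant differs on aggregated rows but not on test rows
  enh_oof <- enhance_collection(src, col, use_oof = TRUE)
  e <- col$endpoints[[1]]
  test_rows <- which(e$split == "test")
  agg_rows <- which(e$split != "test")
  expect_identical(enh_oof$endpoints[[1]]$X[test_rows, ],
                   enh$endpoints[[1]]$X[test_rows, ])
  expect_false(identical(enh_oof$endpoints[[1]]$X[agg_rows, col$d + 1:4],
                         enh$endpoints[[1]]$X[agg_rows, col$d + 1:4]))
})
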