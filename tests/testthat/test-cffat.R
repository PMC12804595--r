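# End-to-end framework behaviour on small synthetic collections.

test_that("greedy trajectories are monotone at accepted steps and never harm validation", {
  col <- related_collection(seed = 11)
  m <- fit_cffat(col, tiny_config(seed = 11))
  for (r in m$greedy_results) {
    expect_true(all(r$accepted_ids %in% r$candidate_order))
    # accepted ids appear in candidate order
    expect_identical(r$accepted_ids,
                     r$candidate_order[r$candidate_order %in% r$accepted_ids])
    if (nrow(r$trajectory)) {
      acc_scores <- r$trajectory$valid_score[r$trajectory$accepted]
      expect_true(all(diff(c(r$baseline_valid_score, acc_scores)) > 0))
    }
    expect_gte(r$final_valid_score, r$baseline_valid_score)
  }
})

test_that("refits under one seed reproduce accepted neighbours and predictions", {
  col <- related_collection(seed = 12, T = 3, sizes = c(50L, 90L, 90L), d = 12)
  m1 <- fit_cffat(col, tiny_config(seed = 5))
  m2 <- fit_cffat(col, tiny_config(seed = 5))
  expect_identical(lapply(m1$greedy_results, `[[`, "accepted_ids"),
                   lapply(m2$greedy_results, `[[`, "accepted_ids"))
  Xte <- col$endpoints[[1]]$X[1:5, ]
  expect_identical(predict_cffat(m1, 1L, Xte), predict_cffat(m2, 1L, Xte))
})

test_that("a single-task collection degenerates to a baseline cascade on train+valid", {
  col <- related_collection(seed = 13, T = 1, sizes = 60L, d = 10)
  m <- fit_cffat(col, tiny_config(seed = 13))
  r <- m$greedy_results[["1"]]
  expect_length(r$accepted_ids, 0L)
  expect_length(r$candidate_order, 0L)
  # final pool = own train + valid rows
  e <- col$endpoints[[1]]
  expect_equal(sort(m$train_pools[["1"]]$row),
               sort(which(e$split %in% c("train", "valid"))))
  ev <- evaluate_cffat(m, col)
  expect_equal(ev$P_avg, ev$per_endpoint$r2[1])
})

test_that("final training pools include own validation rows and never any test row", {
  col <- related_collection(seed = 14)
  m <- fit_cffat(col, tiny_config(seed = 14))
  for (k in seq_along(col$endpoints)) {
    e <- col$endpoints[[k]]
    id <- e$meta$endpoint_id
    pool <- m$train_pools[[as.character(id)]]
    own_valid <- which(e$split == "valid")
    expect_true(all(own_valid %in% pool$row[pool$endpoint_id == id]))
    comp <- m$greedy_results[[as.character(id)]]$best_train_composition
    expect_equal(nrow(pool), sum(comp) + length(own_valid))
  }
  expect_true(leakage_audit(m, col))
})

test_that("framework prediction is the composition of enhancement and the endpoint cascade", {
  col <- related_collection(seed = 15, T = 2, sizes = c(60L, 80L), d = 10)
  m <- fit_cffat(col, tiny_config(seed = 15))
  X <- col$endpoints[[2]]$X[1:8, ]
  direct <- predict(m$endpoint_models[["2"]], enhance_features(m$source, X))
  expect_identical(predict_cffat(m, 2L, X), direct)
  expect_length(predict_cffat(m, 2L, X), 8L)
  expect_error(predict_cffat(m, 99L, X), "unknown endpoint")
})

test_that("evaluation averages endpoint scores without weighting", {
  col <- related_collection(seed = 16)
  m <- fit_cffat(col, tiny_config(seed = 16))
  ev <- evaluate_cffat(m, col)
  expect_equal(ev$P_avg, mean(ev$per_endpoint$r2))
  ev_rmse <- evaluate_cffat(m, col, metric = "rmse")
  expect_equal(ev_rmse$P_avg, mean(ev_rmse$per_endpoint$rmse))
  expect_true(all(ev_rmse$per_endpoint$rmse >= 0))
})

test_that("endpoints below min_valid_rows skip the greedy search", {
  col <- related_collection(seed = 17, T = 3, sizes = c(50L, 90L, 90L), d = 10)
  m <- fit_cffat(col, tiny_config(seed = 17),
                 options = greedy_options(min_valid_rows = 1000L))
  for (r in m$greedy_results) {
    expect_true(r$greedy_skipped)
    expect_length(r$accepted_ids, 0L)
  }
})
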