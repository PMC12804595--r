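# Independent oracle: naive double-loop covariance and distance.
naive_cov <- function(X) {
  n <- nrow(X); d <- ncol(X)
  M <- matrix(0, d, d)
  mu <- colMeans(X)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      M[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) / (n - 1)
    }
  }
  M
}
naive_dist <- function(Xa, Xb) mean(abs(naive_cov(Xa) - naive_cov(Xb)))

test_that("covariance matrix matches the double-loop oracle and hand example", {
  X <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(unclass(covariance_matrix(X)), matrix(4, 2, 2), ignore_attr = TRUE)
  set.seed(42)
  for (k in 1:5) {
    R <- matrix(rnorm(50 * 10), 50, 10)
    expect_equal(unclass(covariance_matrix(R)), naive_cov(R),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # constant column -> zero row and column
  Xc <- cbind(rep(1, 4), rnorm(4))
  M <- covariance_matrix(Xc)
  expect_equal(M[1, ], c(0, 0))
  expect_equal(M[, 1], c(0, 0))
  expect_error(covariance_matrix(matrix(1, 1, 2)), "covariance undefined")
})

test_that("covariance distance matches the oracle, the hand example, and is symmetric", {
  Xa <- rbind(c(1, 2), c(3, 4), c(5, 6))
  Xb <- matrix(0, 3, 2)
  expect_equal(covariance_distance(Xa, Xb), 4)
  expect_equal(covariance_distance(Xa, Xa), 0)
  set.seed(43)
  for (k in 1:5) {
    A <- matrix(rnorm(50 * 10), 50, 10)
    B <- matrix(rnorm(50 * 10), 50, 10)
    expect_equal(covariance_distance(A, B), naive_dist(A, B), tolerance = 1e-10)
    expect_equal(covariance_distance(A, B), covariance_distance(B, A))
  }
  expect_error(covariance_distance(Xa, matrix(0, 3, 3)), "width mismatch")
})

test_that("distance matrix laws hold and an odd endpoint stands out", {
  col <- generate_collection(synth_spec(T = 3, sizes = rep(80L, 3), d = 15,
                                        n_clusters = 2, relatedness = 0.5,
                                        seed = 5))
  # tasks 1 and 3 share cluster 1; task 2 sits alone in cluster 2
  D <- build_distance_matrix(col, use_rows = c("train", "valid"))
  expect_equal(D$D, t(D$D))
  expect_equal(diag(D$D), rep(0, 3))
  expect_true(all(D$D >= 0))
  # oracle: recompute entry (1,3) directly from the drawn matrices
  rows <- function(k) {
    e <- col$endpoints[[k]]
    e$X[e$split %in% c("train", "valid"), , drop = FALSE]
  }
  expect_equal(D$D[1, 3], naive_dist(rows(1), rows(3)), tolerance = 1e-10)
  expect_equal(which.max(rowSums(D$D)), 2L)
})

test_that("neighbour ranking argsorts ascending, excludes self, breaks ties by id", {
  D <- structure(list(D = rbind(c(0, 0.5, 0.2),
                                c(0.5, 0, 0.1),
                                c(0.2, 0.1, 0)),
                      endpoint_ids = c(1L, 2L, 3L)),
                 class = "distance_matrix")
  expect_equal(rank_neighbors(D, 1L), c(3L, 2L))
  expect_equal(rank_neighbors(D, 2L), c(3L, 1L))
  Dtie <- structure(list(D = matrix(1, 3, 3) - diag(3), endpoint_ids = c(7L, 5L, 9L)),
                    class = "distance_matrix")
  expect_equal(rank_neighbors(Dtie, 5L), c(7L, 9L))
  expect_false(5L %in% rank_neighbors(Dtie, 5L))
  expect_error(rank_neighbors(D, 99L), "unknown endpoint")
})

test_that("endpoints with fewer than two usable rows are rejected by name", {
  meta1 <- endpoint_meta(1, 1, 1, 1)
  meta2 <- endpoint_meta(2, 2, 1, 1)
  e1 <- endpoint_dataset(meta1, matrix(rnorm(20), 10, 2), rnorm(10),
                         split = rep("train", 10))
  e2 <- endpoint_dataset(meta2, matrix(rnorm(6), 3, 2), rnorm(3),
                         split = c("train", "test", "test"))
  col <- multitask_collection(list(e1, e2))
  expect_error(build_distance_matrix(col), "endpoint 2")
})
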