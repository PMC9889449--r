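test_that("nearest_neighbors matches the exhaustive search oracle", {
  set.seed(1)
  q <- matrix(rnorm(1500, sd = 10), 500)
  tgt <- matrix(rnorm(1500, sd = 10), 500)
  nn <- nearest_neighbors(q, tgt)
  or <- oracle_nn(q, tgt)
  expect_identical(nn$index, or$index)
  expect_equal(nn$distance, or$distance, tolerance = 1e-12)

  # self-query: identity with distance zero
  self <- nearest_neighbors(tgt, tgt)
  expect_identical(self$index, seq_len(nrow(tgt)))
  expect_equal(max(self$distance), 0)

  expect_equal(nearest_neighbors(matrix(c(0.4, 0, 0), 1),
                                 rbind(c(0, 0, 0), c(1, 0, 0)))$index, 1L)
  expect_error(nearest_neighbors(q, matrix(0, 0, 3)), "empty")
})

test_that("exact distance ties break to the lowest target index", {
  target <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))  # duplicates of index 1 at index 3
  nn <- nearest_neighbors(rbind(c(0, 0, 0), c(1, 0, 0)), target)
  expect_identical(nn$index, c(1L, 1L))
})

test_that("icp_register is exact for trivial and small-perturbation cases", {
  cl <- structured_cloud(600, seed = 2)

  same <- icp_register(cl, cl)
  expect_lte(same$iterations, 2)
  expect_true(same$converged)
  expect_equal(tail(same$rms_history, 1), 0, tolerance = 1e-12)

  frozen <- icp_register(cl, apply_transform(random_rigid_transform(seed = 1), cl),
                         max_iter = 0)
  expect_equal(transform_matrix(frozen$transform), diag(4))
  expect_false(frozen$converged)
  expect_identical(frozen$iterations, 0L)

  tr <- random_rigid_transform(5, 2, seed = 11)
  fit <- icp_register(cl, apply_transform(tr, cl), max_iter = 200, tol = 1e-9)
  expect_lt(tail(fit$rms_history, 1), 1e-6)
  expect_lt(max(row_norms_test(apply_transform(fit$transform, cl) -
                               apply_transform(tr, cl))), 1e-6)
})

test_that("matched RMS is monotone non-increasing across iterations", {
  cl <- structured_cloud(500, seed = 9)
  for (s in 1:10) {
    tr <- random_rigid_transform(10, 5, seed = 200 + s)
    res <- icp_register(cl, apply_transform(tr, cl), max_iter = 150, tol = 1e-9)
    expect_true(all(diff(res$rms_history) <= 1e-12))
  }
})

test_that("a grossly wrong start still terminates monotonically", {
  cl <- structured_cloud(400, seed = 14)
  res <- icp_register(cl, apply_transform(random_rigid_transform(170, 80, seed = 5), cl),
                      max_iter = 80)
  expect_lte(res$iterations, 80)
  expect_true(all(diff(res$rms_history) <= 1e-12))
})
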