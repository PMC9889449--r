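test_that("distance_map matches the exhaustive nearest-point oracle", {
  set.seed(3)
  q <- matrix(rnorm(3000, sd = 5), 1000)
  ref <- matrix(rnorm(3000, sd = 5), 1000)
  dm <- distance_map(q, ref)
  expect_equal(dm$per_point, oracle_nn(q, ref)$distance, tolerance = 1e-12)
  expect_equal(dm$max_distance, max(dm$per_point))

  expect_equal(max(distance_map(ref, ref)$per_point), 0)
  expect_equal(distance_map(matrix(c(2, 0, 0), 1),
                            rbind(c(0, 0, 0), c(1, 0, 0)))$per_point, 1)
  expect_error(distance_map(q, matrix(0, 0, 3)), "empty")
})

test_that("point-to-surface distances agree with the brute-force triangle oracle", {
  soup <- random_triangle_soup(n_tri = 120, seed = 21)
  set.seed(22)
  q <- matrix(runif(300, -2, 12), 100)
  fast <- distance_map(q, soup, method = "triangle")$per_point
  brute <- ersr:::.cpp_point_triangle_dist(soup$vertices, soup$faces, q)
  expect_equal(fast, brute, tolerance = 1e-10)
})

test_that("histogram bins span [0, max] with the documented first-bin width", {
  # worked example: max 0.56 mm with 11 bins gives ~0.05 mm wide bins
  d <- c(seq(0, 0.56, length.out = 50))
  h <- distance_histogram(d, n_bins = 11)
  expect_equal(h$bin_edges[1], 0)
  expect_equal(tail(h$bin_edges, 1), 0.56)
  expect_equal(h$bin_edges[2], 0.56 / 11)
  expect_equal(sum(h$frequencies), 1, tolerance = 1e-12)

  h0 <- distance_histogram(rep(0, 10))
  expect_true(h0$degenerate)
  expect_equal(h0$first_bin_frequency, 1)

  set.seed(10)
  u <- runif(20000)
  hu <- distance_histogram(u, n_bins = 10)
  expect_equal(hu$first_bin_frequency, 0.1, tolerance = 0.02)  # binomial expectation
})

test_that("first-bin frequency is invariant under joint rigid motion", {
  set.seed(6)
  a <- matrix(rnorm(900, sd = 8), 300)
  b <- matrix(rnorm(900, sd = 8), 300)
  h1 <- distance_histogram(distance_map(a, b))
  tr <- random_rigid_transform(seed = 31)
  h2 <- distance_histogram(distance_map(apply_transform(tr, a), apply_transform(tr, b)))
  expect_equal(h2$first_bin_frequency, h1$first_bin_frequency, tolerance = 1e-9)
})

test_that("hausdorff_distance matches the double-loop oracle", {
  expect_equal(hausdorff_distance(matrix(1:3, 1), matrix(1:3, 1)), 0)
  expect_equal(hausdorff_distance(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1)), 1)
  set.seed(7)
  a <- matrix(rnorm(600), 200)
  b <- matrix(rnorm(750), 250)
  expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b), tolerance = 1e-12)
  expect_error(hausdorff_distance(a, matrix(0, 0, 3)), "empty")
})

test_that("fiducial localization error reports per-landmark distances", {
  nm <- c("M1", "M2", "M3")
  truth <- landmark_set(nm, matrix(rnorm(9), 3), "fiducial")
  expect_equal(max(fiducial_localization_error(truth, truth)$per_point), 0)

  shifted <- landmark_set(nm, truth$coords + rep(c(0, 0, 0.5), each = 3), "fiducial")
  expect_equal(unname(fiducial_localization_error(shifted, truth)$per_point),
               rep(0.5, 3))

  other <- landmark_set(c("M1", "M2", "X9"), matrix(rnorm(9), 3), "fiducial")
  expect_error(fiducial_localization_error(other, truth), "mismatch")

  # isotropic sigma per axis gives RMS ~ sigma * sqrt(3) (chi distribution)
  set.seed(9)
  n <- 2000
  obs <- matrix(rnorm(3 * n, sd = 0.4), n)
  fle <- fiducial_localization_error(obs, matrix(0, n, 3))
  expect_equal(fle$rms, 0.4 * sqrt(3), tolerance = 0.05)
})
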