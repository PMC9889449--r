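test_that("apply_transform handles identity, translation and rotation exactly", {
  cloud <- matrix(rnorm(30), 10)
  expect_equal(apply_transform(identity_transform(), cloud), cloud)

  tr <- rigid_transform(translation = c(1, 2, 3))
  expect_equal(apply_transform(tr, matrix(0, 1, 3)), matrix(c(1, 2, 3), 1))

  rot90z <- rigid_transform(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3))
  expect_equal(apply_transform(rot90z, matrix(c(1, 0, 0), 1)),
               matrix(c(0, 1, 0), 1), tolerance = 1e-12)
})

test_that("composition matches the homogeneous matrix-product oracle", {
  expect_equal(transform_matrix(compose_transforms(identity_transform(),
                                                   random_rigid_transform(seed = 1))),
               transform_matrix(random_rigid_transform(seed = 1)))
  for (s in 1:20) {
    t1 <- random_rigid_transform(seed = 2 * s)
    t2 <- random_rigid_transform(seed = 2 * s + 1)
    expect_equal(transform_matrix(compose_transforms(t2, t1)),
                 oracle_compose_matrix(t2, t1), tolerance = 1e-12)
    # compose(T2, T1) applies T1 first
    p <- matrix(rnorm(9), 3)
    expect_equal(apply_transform(compose_transforms(t2, t1), p),
                 apply_transform(t2, apply_transform(t1, p)), tolerance = 1e-9)
  }
})

test_that("inversion round-trips and double inversion is exact", {
  expect_equal(transform_matrix(invert_transform(identity_transform())), diag(4))
  tr <- rigid_transform(translation = c(3, -1, 2))
  expect_equal(invert_transform(tr)$translation, c(-3, 1, -2))
  for (s in 1:10) {
    tr <- random_rigid_transform(seed = s)
    expect_equal(transform_matrix(compose_transforms(tr, invert_transform(tr))),
                 diag(4), tolerance = 1e-9)
    expect_equal(transform_matrix(invert_transform(invert_transform(tr))),
                 transform_matrix(tr), tolerance = 1e-12)
    p <- matrix(rnorm(15, sd = 30), 5)
    expect_equal(apply_transform(invert_transform(tr), apply_transform(tr, p)), p,
                 tolerance = 1e-9)
  }
})

test_that("rigid transforms preserve pairwise distances", {
  cloud <- matrix(rnorm(60, sd = 40), 20)
  for (s in 1:10) {
    tr <- random_rigid_transform(seed = 100 + s)
    expect_equal(as.matrix(dist(apply_transform(tr, cloud))), as.matrix(dist(cloud)),
                 tolerance = 1e-9)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  }
})

test_that("reflections and non-orthonormal rotations are rejected", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "improper|reflection")
  expect_error(rigid_transform(matrix(rnorm(9), 3)), "orthonormal")
  expect_error(transform_from_matrix(diag(c(1, 1, -1, 1))), "improper")
})

test_that("triangle_mesh validates faces and removes degenerate ones", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3), c(1, 2, 3), c(1, 1, 2)))
  expect_equal(nrow(m$faces), 2)  # duplicate and zero-area faces dropped
  expect_error(triangle_mesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(triangle_mesh(matrix(c(0, 0, NA), 1), matrix(c(1, 1, 1), 1)), "finite")
})

test_that("watertightness check distinguishes closed from open surfaces", {
  sphere <- make_truth_mesh(seed = 3, subdivisions = 2)
  expect_true(mesh_is_watertight(sphere))
  open_patch <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                              matrix(c(1, 2, 3), 1))
  expect_false(mesh_is_watertight(open_patch))
})
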