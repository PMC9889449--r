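test_that("landmark_set validates names, roles and coordinates", {
  ls <- landmark_set(c("M1", "M2", "M3", "C1"), matrix(rnorm(12), 4))
  expect_equal(ls$roles, c("fiducial", "fiducial", "fiducial", "control"))
  expect_error(landmark_set(c("M1", "M1"), matrix(0, 2, 3)), "unique")
  expect_equal(rownames(landmark_coords(ls, role = "control")), "C1")
})

test_that("landmark fit recovers exact rigid relations", {
  set.seed(42)
  src <- matrix(rnorm(15, sd = 40), 5)

  fit0 <- fit_landmark_transform(src, src)
  expect_equal(transform_matrix(fit0), diag(4), tolerance = 1e-9)

  fit_t <- fit_landmark_transform(src, sweep(src, 2, -c(1, 2, 3)))
  expect_equal(fit_t$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit_t$translation, c(1, 2, 3), tolerance = 1e-9)

  for (s in 1:25) {
    tr <- random_rigid_transform(seed = s)
    fit <- fit_landmark_transform(src, apply_transform(tr, src))
    expect_lt(max(row_norms_test(apply_transform(fit, src) - apply_transform(tr, src))),
              1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate landmark configurations are rejected", {
  expect_error(fit_landmark_transform(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "insufficient")
  line <- cbind(1:5, 0, 0)
  expect_error(fit_landmark_transform(line, line + 1), "collinear|degenerate")
  expect_error(fit_landmark_transform(matrix(rnorm(12), 4), matrix(rnorm(15), 5)),
               "mismatch")
})

test_that("fit never returns a reflection, even for mirrored input", {
  set.seed(8)
  src <- matrix(rnorm(15, sd = 20), 5)
  mirrored <- src %*% diag(c(-1, 1, 1))  # best orthogonal map would be a reflection
  fit <- fit_landmark_transform(src, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("registration_error matches hand arithmetic and displacement oracle", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  dst <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  rep <- registration_error(src, dst, identity_transform())
  expect_equal(unname(rep$per_point), c(0, 0, 1))
  expect_equal(rep$rms, sqrt(1 / 3))

  set.seed(5)
  pairs <- matrix(rnorm(18, sd = 30), 6)
  tr <- random_rigid_transform(seed = 77)
  moved <- apply_transform(tr, pairs)
  expect_equal(registration_error(pairs, moved, tr)$rms, 0, tolerance = 1e-9)
  expect_equal(registration_error(pairs, moved, identity_transform())$rms,
               sqrt(mean(rowSums((moved - pairs)^2))))
  expect_error(registration_error(matrix(0, 0, 3), matrix(0, 0, 3)), "empty")
})

test_that("FRE grows with fiducial noise and is zero without it", {
  set.seed(30)
  src <- matrix(rnorm(15, sd = 40), 5)
  tr <- random_rigid_transform(seed = 3)
  dst0 <- apply_transform(tr, src)
  fre_at <- function(sigma) {
    mean(vapply(1:100, function(s) {
      set.seed(1000 + s)
      dst <- dst0 + matrix(rnorm(15, sd = sigma), 5)
      fit <- fit_landmark_transform(src, dst)
      registration_error(src, dst, fit)$rms
    }, numeric(1)))
  }
  fres <- vapply(c(0, 0.2, 0.5, 1.0), fre_at, numeric(1))
  expect_equal(fres[1], 0, tolerance = 1e-9)
  expect_true(all(diff(fres) > 0))
})
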