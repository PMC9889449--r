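# Unit tests for the synthetic fixture generator. The full-size phantom is
# exercised by the acceptance suite; here smaller geometry keeps tests fast.

test_that("truth mesh generation is deterministic, watertight and asymmetric", {
  m1 <- make_truth_mesh(seed = 5, subdivisions = 3)
  m2 <- make_truth_mesh(seed = 5, subdivisions = 3)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_false(identical(make_truth_mesh(seed = 6, subdivisions = 3)$vertices,
                         m1$vertices))
  expect_true(mesh_is_watertight(m1))
  expect_gt(ersr:::rotational_asymmetry(m1), 1)  # > 1 mm RMS under 30 deg rotations
})

test_that("landmarks are named, on-surface, spread and usable for fitting", {
  m <- make_truth_mesh(seed = 5, subdivisions = 4)
  lm <- place_landmarks(m, seed = 2)
  expect_setequal(lm$names, c(paste0("M", 1:5), paste0("C", 1:12)))
  expect_equal(sum(lm$roles == "fiducial"), 5)
  fid <- landmark_coords(lm, "fiducial")
  expect_gt(min(dist(fid)), 20)
  # non-collinear: the rigid fit accepts them
  expect_s3_class(fit_landmark_transform(fid, fid), "rigid_transform")
  # on-surface (landmarks are mesh vertices)
  expect_equal(max(nearest_neighbors(lm$coords, m$vertices)$distance), 0)
})

test_that("CT degradation of a sphere stays within the quantization bound", {
  s <- icosphere_mesh(50, subdivisions = 4)
  ct <- degrade_to_ct(s, 0.39, 1.5)
  r <- row_norms_test(ct$vertices)
  expect_lt(max(abs(r - 50)), 1.6)            # within ~ the slice thickness
  expect_lt(sqrt(mean((r - 50)^2)), 0.3)      # partial-volume isosurface is much closer
  # determinism
  ct2 <- degrade_to_ct(s, 0.39, 1.5)
  expect_identical(ct$vertices, ct2$vertices)
})

test_that("finer slices reduce the RMS surface error monotonically", {
  s <- icosphere_mesh(20, subdivisions = 3)
  rms <- vapply(c(1.5, 0.75, 0.375), function(sl) {
    r <- row_norms_test(degrade_to_ct(s, 0.39, sl)$vertices)
    sqrt(mean((r - 20)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("voxel budget guard triggers on runaway grids", {
  s <- icosphere_mesh(30, subdivisions = 2)
  expect_error(degrade_to_ct(s, 0.01, 0.01), "budget")
})

test_that("scanner simulation calibrates to its noise level and pose", {
  m <- make_truth_mesh(seed = 5, subdivisions = 4)  # 2562 vertices
  expect_identical(simulate_scanner(m, seed = 1, noise_sigma = 0)$vertices, m$vertices)

  sc <- simulate_scanner(m, seed = 1, noise_sigma = 0.05)
  disp <- sqrt(mean(rowSums((sc$vertices - m$vertices)^2)))
  expect_equal(disp, 0.05 * sqrt(3), tolerance = 0.05)
  expect_identical(simulate_scanner(m, seed = 1, noise_sigma = 0.05)$vertices, sc$vertices)

  pose <- random_rigid_transform(seed = 9)
  moved <- simulate_scanner(m, seed = 1, noise_sigma = 0, pose = pose)
  expect_equal(moved$vertices, apply_transform(pose, m$vertices))
})

test_that("palpation simulation round-trips through register_to_drf", {
  m <- make_truth_mesh(seed = 5, subdivisions = 3)
  lm <- place_landmarks(m, seed = 2)
  pose <- random_rigid_transform(seed = 3)

  exact <- simulate_palpation(lm, pose, seed = 1, noise_sigma = 0)
  expect_equal(unname(exact$coords), apply_transform(pose, lm$coords))
  rec <- register_to_drf(lm, exact)
  expect_equal(transform_matrix(rec), transform_matrix(pose), tolerance = 1e-9)

  # noise calibration at many points
  big <- landmark_set(sprintf("M%d", 1:1000), matrix(rnorm(3000, sd = 50), 1000),
                      "fiducial")
  noisy <- simulate_palpation(big, identity_transform(), seed = 4, noise_sigma = 0.25)
  fle <- fiducial_localization_error(noisy, big)
  expect_equal(fle$rms, 0.25 * sqrt(3), tolerance = 0.1)
})

test_that("landmark pick perturbation is seeded and sigma-calibrated", {
  lm <- landmark_set(sprintf("C%d", 1:1000), matrix(rnorm(3000, sd = 50), 1000),
                     "control")
  expect_identical(perturb_landmark_picks(lm, seed = 1, sigma = 0)$coords, lm$coords)
  p1 <- perturb_landmark_picks(lm, seed = 1, sigma = 0.5)
  p2 <- perturb_landmark_picks(lm, seed = 1, sigma = 0.5)
  p3 <- perturb_landmark_picks(lm, seed = 2, sigma = 0.5)
  expect_identical(p1$coords, p2$coords)
  expect_false(identical(p1$coords, p3$coords))
  expect_equal(fiducial_localization_error(p1, lm)$rms, 0.5 * sqrt(3),
               tolerance = 0.1)
})

test_that("the assembled phantom records consistent frames and ground truth", {
  ph <- synthetic_phantom(seed = 3, resolutions = c(A = 0.8), slice_mm = 2,
                          size = 120, subdivisions = 4)
  expect_s3_class(ph, "synthetic_phantom")
  # truth landmarks on truth mesh
  expect_lt(max(nearest_neighbors(ph$landmarks_truth$coords,
                                  ph$truth_mesh$vertices)$distance), 1e-6)
  # recorded transforms are proper rigid
  for (tr in c(list(ph$transforms$truth_to_scanner, ph$transforms$scanner_to_drf),
               ph$transforms$truth_to_ct))
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  # dicom landmark observations lie on the CT mesh (vertex snapping)
  expect_equal(max(nearest_neighbors(ph$dicom_landmarks$A$coords,
                                     ph$ct_meshes$A$vertices)$distance), 0)
  # same seed regenerates identically
  ph2 <- synthetic_phantom(seed = 3, resolutions = c(A = 0.8), slice_mm = 2,
                           size = 120, subdivisions = 4)
  expect_identical(ph$scanner_mesh$vertices, ph2$scanner_mesh$vertices)
  expect_identical(ph$ct_meshes$A$vertices, ph2$ct_meshes$A$vertices)
})
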