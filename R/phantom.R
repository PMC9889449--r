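# Seeded synthetic study fixture: a bone-like ground-truth surface, its
# CT-degraded counterparts at several in-plane resolutions, a noisy
# scanner-like copy, landmark observations per frame, and palpation data
# in a tracked reference frame. Everything is reproducible from (seed,
# params); a manifest records both.

#' Generate a bone-like ground-truth surface
#'
#' An icosphere (subdivided icosahedron) scaled to an ellipsoid and
#' modulated by seeded smooth Gaussian bumps and indentations on the
#' direction sphere. The result is watertight, single-shell and --
#' verified at generation time -- rotationally non-symmetric, so that
#' rigid registration against it is well posed. The default ~200 mm
#' extent matches a head-sized CT field of view.
#'
#' @param seed Integer seed.
#' @param size Largest ellipsoid diameter, mm.
#' @param axes_ratio Relative semi-axes (scaled so max diameter = `size`).
#' @param n_bumps Number of smooth radial features.
#' @param bump_amp Range of relative bump amplitudes (fractions of the
#'   local radius; negative draws become indentations).
#' @param bump_width Range of angular bump widths, radians.
#' @param subdivisions Icosphere subdivision level (5 gives 10242
#'   vertices / 20480 faces, a vertex spacing of ~2-3 mm at this size).
#' @return A [triangle_mesh()].
#' @export
make_truth_mesh <- function(seed, size = 200, axes_ratio = c(1, 0.85, 0.7),
                            n_bumps = 40, bump_amp = c(0.05, 0.15),
                            bump_width = c(0.06, 0.20), subdivisions = 5) {
  stopifnot(size > 0, length(axes_ratio) == 3L)
  base <- icosphere(subdivisions)
  semi <- axes_ratio / max(axes_ratio) * size / 2
  with_seed(seed, {
    centres <- matrix(rnorm(3 * n_bumps), n_bumps, 3L)
    centres <- centres / row_norms(centres)
    amp <- stats::runif(n_bumps, bump_amp[1], bump_amp[2]) *
      sample(c(-1, 1), n_bumps, replace = TRUE)
    wid <- stats::runif(n_bumps, bump_width[1], bump_width[2])
  })
  dirs <- base$vertices  # unit vectors
  radial <- rep(1, nrow(dirs))
  for (k in seq_len(n_bumps)) {
    ang <- acos(pmin(1, pmax(-1, dirs %*% centres[k, ])))
    radial <- radial + amp[k] * exp(-ang^2 / (2 * wid[k]^2))
  }
  v <- dirs * radial
  v <- sweep(v, 2L, semi, `*`)
  mesh <- triangle_mesh(v, base$faces)
  sym <- rotational_asymmetry(mesh)
  if (sym <= 1)
    stop("generated surface is too close to rotationally symmetric; choose other params",
         call. = FALSE)
  mesh
}

# Minimum over the three principal axes of the RMS nearest-vertex distance
# between the mesh and itself rotated by 30 degrees about that axis.
rotational_asymmetry <- function(mesh, angle_deg = 30) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  ax <- svd(vc)$v  # principal axes
  worst <- Inf
  for (a in 1:3) {
    rot <- rotation_about_axis(ax[, a], angle_deg * pi / 180)
    vr <- vc %*% t(rot)
    worst <- min(worst, sqrt(mean(nearest_neighbors(vr, vc)$distance^2)))
  }
  worst
}

# Unit icosphere: subdivided icosahedron, vertices normalized to the sphere.
icosphere <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / vnorm(m)
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4L * t - 3L, ] <- c(a, ab, ca)
      nf[4L * t - 2L, ] <- c(b, bc, ab)
      nf[4L * t - 1L, ] <- c(c, ca, bc)
      nf[4L * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Sample points uniformly over a mesh surface
#'
#' Area-weighted face selection with uniform barycentric draws. Unlike
#' the mesh vertices themselves, the sample carries no lattice
#' regularity; regular samplings of smooth surfaces admit spurious ICP
#' local minima at one-lattice-step offsets, so irregular clouds are the
#' right test bed for exact-recovery experiments.
#'
#' @param mesh A [triangle_mesh()].
#' @param n Number of points.
#' @param seed Integer seed.
#' @return n x 3 matrix of on-surface points.
#' @export
sample_surface_points <- function(mesh, n, seed = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  w <- row_norms(cr)
  with_seed(seed, {
    fi <- sample.int(nrow(f), n, replace = TRUE, prob = w)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    a[fi, , drop = FALSE] + (r1 * (1 - r2)) * e1[fi, , drop = FALSE] +
      (r1 * r2) * e2[fi, , drop = FALSE]
  })
}

#' Place named fiducial and control landmarks on a surface
#'
#' Five fiducials (M1-M5) are spread over one aspect of the surface by
#' farthest-point sampling (guaranteeing a pairwise spacing of at least
#' 20 mm and non-collinearity, as a usable fiducial configuration
#' requires), and twelve control points (C1-C12) are spread over the
#' remainder. All landmarks sit exactly on mesh vertices.
#'
#' @param mesh A [triangle_mesh()].
#' @param seed Integer seed (selects the aspect direction).
#' @param min_fiducial_spacing Minimum pairwise fiducial distance, mm.
#' @return A [landmark_set()] with 17 entries, frame `"truth"`.
#' @export
place_landmarks <- function(mesh, seed, min_fiducial_spacing = 20) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  dirs <- sweep(v, 2L, ctr)
  dirs <- dirs / row_norms(dirs)
  with_seed(seed, {
    aspect <- rnorm(3)
    aspect <- aspect / vnorm(aspect)
    jitter_start <- sample.int(nrow(v), 1L)
  })
  cosang <- as.numeric(dirs %*% aspect)
  fid_pool <- which(cosang > cos(70 * pi / 180))
  ctl_pool <- which(cosang <= cos(80 * pi / 180))
  fid <- farthest_points(v, fid_pool, 5L, start = fid_pool[which.max(cosang[fid_pool])])
  if (min(stats::dist(v[fid, ])) < min_fiducial_spacing)
    stop("cannot place fiducials with required spacing; increase mesh size", call. = FALSE)
  ctl <- farthest_points(v, ctl_pool, 12L,
                         start = ctl_pool[(jitter_start %% length(ctl_pool)) + 1L])
  landmark_set(c(paste0("M", 1:5), paste0("C", 1:12)),
               rbind(v[fid, ], v[ctl, ]),
               c(rep("fiducial", 5), rep("control", 12)),
               frame = "truth")
}

# Greedy farthest-point sampling of k vertices among `pool` indices.
farthest_points <- function(v, pool, k, start) {
  sel <- start
  dmin <- row_norms(sweep(v[pool, , drop = FALSE], 2L, v[start, ]))
  while (length(sel) < k) {
    nxt <- pool[which.max(dmin)]
    sel <- c(sel, nxt)
    dmin <- pmin(dmin, row_norms(sweep(v[pool, , drop = FALSE], 2L, v[nxt, ])))
  }
  sel
}

#' Degrade a surface to CT acquisition resolution
#'
#' Emulates the geometric effect of CT imaging and threshold
#' segmentation: the closed surface is converted to a partial-volume
#' occupancy grid sampled at the CT spacing (`pixel_mm` in-plane,
#' `slice_mm` between slices) and a surface is re-extracted as the 50%
#' isosurface. Intensity physics is deliberately not modelled -- the
#' variable of interest is geometric resolution only. The output
#' approximates the input with a quantization error bounded by about
#' half a voxel diagonal (in practice far less on smooth surfaces, since
#' the isosurface interpolates the partial-volume fractions, just as
#' marching cubes on real CT intensities interpolates across the
#' partial-volume transition voxel).
#'
#' Deterministic: identical inputs give identical outputs.
#'
#' @param mesh A closed [triangle_mesh()].
#' @param pixel_mm In-plane pixel spacing, mm (e.g. 0.39 / 0.43 / 0.47).
#' @param slice_mm Slice thickness, mm (e.g. 1.5).
#' @param supersample Sub-columns per voxel axis for the partial-volume
#'   estimate (see [voxelize()]); 1 gives a binary centre-sample grid.
#' @param max_cells Guard against runaway grids (default 1e9 cells).
#' @return A [triangle_mesh()].
#' @export
degrade_to_ct <- function(mesh, pixel_mm, slice_mm, supersample = 3, max_cells = 1e9) {
  stopifnot(inherits(mesh, "triangle_mesh"), pixel_mm > 0, slice_mm > 0)
  vg <- voxelize(mesh, c(pixel_mm, pixel_mm, slice_mm), supersample = supersample,
                 max_cells = max_cells)
  iso <- .cpp_marching_tets(vg$occupancy, vg$dims, vg$origin, vg$spacing, 0.5 * 255)
  if (nrow(iso$faces) == 0L) stop("isosurface is empty; grid too coarse for this mesh",
                                  call. = FALSE)
  triangle_mesh(iso$vertices, iso$faces)
}

#' Voxelize a closed surface into a partial-volume occupancy grid
#'
#' Occupancy is the fraction of each voxel's volume inside the closed
#' surface, on a 0..255 byte scale (a voxel's coordinate refers to its
#' centre; grid indices are 0-based). The fraction is computed from
#' `supersample^2` sub-columns through the voxel footprint, with the
#' inside intervals along z resolved analytically from surface-crossing
#' parity, and two voxels of padding surround the mesh bounding box.
#' With `supersample = 1` the result is the classic binary
#' centre-in-polyhedron grid (0 or 255 everywhere).
#'
#' @param mesh A closed [triangle_mesh()].
#' @param spacing Length-3 voxel spacing `(sx, sy, sz)`, mm.
#' @param supersample Sub-columns per in-plane axis (default 3).
#' @param max_cells Cell-count guard.
#' @return List `occupancy` (raw vector, x fastest), `dims`, `origin`
#'   (centre of voxel (0,0,0)), `spacing`.
#' @export
voxelize <- function(mesh, spacing, supersample = 3, max_cells = 1e9) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), supersample >= 1)
  lo <- apply(mesh$vertices, 2L, min) - 2 * spacing
  hi <- apply(mesh$vertices, 2L, max) + 2 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dims)) > max_cells)
    stop(sprintf("voxel budget exceeded: %.3g cells", prod(as.numeric(dims))), call. = FALSE)
  occ <- .cpp_voxelize(mesh$vertices, mesh$faces, lo, spacing, dims,
                       as.integer(supersample))
  list(occupancy = occ, dims = dims, origin = lo, spacing = spacing)
}

#' Simulate a surface-scanner acquisition of a mesh
#'
#' Perturbs every vertex with isotropic Gaussian noise of standard
#' deviation `noise_sigma` per axis (default 0.05 mm, a typical
#' structured-light scanner accuracy) and then moves the mesh rigidly by
#' `pose` into the "scanner frame". The pose is the ground-truth
#' transform a registration should recover.
#'
#' @param mesh Input [triangle_mesh()] (truth frame).
#' @param seed Integer seed.
#' @param noise_sigma Per-axis vertex noise, mm (>= 0).
#' @param pose [rigid_transform()] truth -> scanner frame.
#' @return A [triangle_mesh()] in the scanner frame.
#' @export
simulate_scanner <- function(mesh, seed, noise_sigma = 0.05, pose = identity_transform()) {
  stopifnot(noise_sigma >= 0)
  v <- mesh$vertices
  if (noise_sigma > 0)
    v <- v + with_seed(seed, matrix(rnorm(length(v), 0, noise_sigma), nrow(v), 3L))
  apply_transform(pose, triangle_mesh(v, mesh$faces))
}

#' Simulate palpation of landmarks with a tracked pointer
#'
#' Maps landmark coordinates into the dynamic-reference-frame (DRF)
#' coordinate system by `drf_pose` and adds isotropic Gaussian noise of
#' `noise_sigma` per axis (default 0.25 mm, a typical optical-tracker
#' pointer accuracy).
#'
#' @param landmarks A [landmark_set()] (scanner frame).
#' @param drf_pose [rigid_transform()] scanner -> DRF frame.
#' @param seed Integer seed.
#' @param noise_sigma Per-axis noise, mm (>= 0).
#' @return A [landmark_set()] in frame `"drf"`.
#' @export
simulate_palpation <- function(landmarks, drf_pose, seed, noise_sigma = 0.25) {
  stopifnot(inherits(landmarks, "landmark_set"), noise_sigma >= 0)
  co <- apply_transform(drf_pose, landmarks$coords)
  if (noise_sigma > 0)
    co <- co + with_seed(seed, matrix(rnorm(length(co), 0, noise_sigma), nrow(co), 3L))
  landmark_set(landmarks$names, co, landmarks$roles, frame = "drf")
}

#' Perturb landmark picks with isotropic Gaussian noise
#'
#' Emulates imprecise manual pointing of markers on an image or scan --
#' the fiducial localization error that paired-point registration is
#' sensitive to.
#'
#' @param landmarks A [landmark_set()].
#' @param seed Integer seed.
#' @param sigma Per-axis noise, mm (>= 0).
#' @return A [landmark_set()] in the same frame.
#' @export
perturb_landmark_picks <- function(landmarks, seed, sigma) {
  stopifnot(inherits(landmarks, "landmark_set"), sigma >= 0)
  co <- landmarks$coords
  if (sigma > 0)
    co <- co + with_seed(seed, matrix(rnorm(length(co), 0, sigma), nrow(co), 3L))
  landmark_set(landmarks$names, co, landmarks$roles, frame = landmarks$frame)
}

#' Generate the full synthetic registration study fixture
#'
#' Builds the ground-truth surface with named landmarks, a CT-degraded
#' mesh per resolution (each in its own randomly posed "CT frame"), a
#' noisy scanner mesh in a "scanner frame", and palpated landmarks in a
#' "DRF frame"; all inter-frame transforms are recorded as ground truth.
#'
#' Landmark observations per dataset:
#' * `dicom_landmarks[[res]]` -- truth landmarks mapped into the CT frame
#'   and snapped to the nearest CT-mesh vertex. Snapping models the fact
#'   that markers can only be localized on the resolution-limited
#'   reconstruction, which is what makes paired-point registration
#'   resolution sensitive. Snapping is deterministic per resolution.
#' * `scanner_landmarks` -- truth landmarks mapped into the scanner frame
#'   plus the scanner's ~0.05 mm localization noise (the scanner's native
#'   resolution is far below the mesh vertex spacing, so no snapping).
#' * `palpated_landmarks` -- scanner-frame landmarks mapped to the DRF
#'   with 0.25 mm pointer noise.
#'
#' Additional manual pick imprecision should be layered on top with
#' [perturb_landmark_picks()].
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param resolutions Named in-plane pixel spacings, mm. `NULL` disables
#'   CT degradation (the CT mesh is an exact posed copy of the truth
#'   mesh -- the noise-free limit).
#' @param slice_mm CT slice thickness, mm.
#' @param scanner_sigma Scanner vertex noise, mm.
#' @param scanner_landmark_sigma Scanner landmark localization noise, mm.
#' @param palpation_sigma Pointer palpation noise, mm.
#' @param pose_angle_deg,pose_translation Magnitude of the random
#'   inter-frame poses.
#' @param ... Passed to [make_truth_mesh()].
#' @return Object of class `synthetic_phantom`; see Details.
#' @export
synthetic_phantom <- function(seed, resolutions = c(A = 0.39, B = 0.43, C = 0.47),
                              slice_mm = 1.5, scanner_sigma = 0.05,
                              scanner_landmark_sigma = 0.05, palpation_sigma = 0.25,
                              pose_angle_deg = 20, pose_translation = 30, ...) {
  seed <- as.integer(seed)
  truth <- make_truth_mesh(seed, ...)
  lm_truth <- place_landmarks(truth, seed + 1L)
  t_scanner <- random_rigid_transform(pose_angle_deg, pose_translation, seed = seed + 2L)
  t_drf <- random_rigid_transform(pose_angle_deg, pose_translation, seed = seed + 3L)
  scanner <- simulate_scanner(truth, seed + 4L, noise_sigma = scanner_sigma,
                              pose = t_scanner)
  lm_scanner <- landmark_set(lm_truth$names,
                             apply_transform(t_scanner, lm_truth$coords),
                             lm_truth$roles, frame = "scanner")
  if (scanner_landmark_sigma > 0)
    lm_scanner <- perturb_landmark_picks(lm_scanner, seed + 5L, scanner_landmark_sigma)
  palpated <- simulate_palpation(lm_scanner, t_drf, seed + 6L,
                                 noise_sigma = palpation_sigma)
  ct_meshes <- list()
  dicom_landmarks <- list()
  t_ct <- list()
  if (is.null(resolutions)) resolutions <- c(exact = NA_real_)
  for (k in seq_along(resolutions)) {
    res <- names(resolutions)[k]
    t_ct[[res]] <- random_rigid_transform(pose_angle_deg, pose_translation,
                                          seed = seed + 10L + k)
    m <- if (is.na(resolutions[k])) truth
         else degrade_to_ct(truth, resolutions[k], slice_mm)
    ct_meshes[[res]] <- apply_transform(t_ct[[res]], m)
    lm_ct <- apply_transform(t_ct[[res]], lm_truth$coords)
    if (!is.na(resolutions[k])) {
      snap <- .cpp_kdtree_query(points_kdtree(ct_meshes[[res]]$vertices,
                                              host = ct_meshes[[res]]), lm_ct)
      lm_ct <- ct_meshes[[res]]$vertices[snap$index, , drop = FALSE]
    }
    dicom_landmarks[[res]] <- landmark_set(lm_truth$names, lm_ct, lm_truth$roles,
                                           frame = "dicom")
  }
  structure(list(
    truth_mesh = truth, scanner_mesh = scanner, ct_meshes = ct_meshes,
    landmarks_truth = lm_truth, scanner_landmarks = lm_scanner,
    dicom_landmarks = dicom_landmarks, palpated_landmarks = palpated,
    transforms = list(truth_to_scanner = t_scanner, truth_to_ct = t_ct,
                      scanner_to_drf = t_drf),
    seed = seed,
    params = list(resolutions = resolutions, slice_mm = slice_mm,
                  scanner_sigma = scanner_sigma,
                  scanner_landmark_sigma = scanner_landmark_sigma,
                  palpation_sigma = palpation_sigma,
                  pose_angle_deg = pose_angle_deg,
                  pose_translation = pose_translation, dots = list(...))),
    class = "synthetic_phantom")
}

#' @export
print.synthetic_phantom <- function(x, ...) {
  cat(sprintf("synthetic_phantom (seed %d)\n", x$seed))
  cat(sprintf("  truth: %d vertices; scanner: %d vertices\n",
              nrow(x$truth_mesh$vertices), nrow(x$scanner_mesh$vertices)))
  for (res in names(x$ct_meshes))
    cat(sprintf("  CT %s: %d vertices\n", res, nrow(x$ct_meshes[[res]]$vertices)))
  invisible(x)
}

#' Default HRPR placements for a synthetic phantom
#'
#' Three rectangles tangent to the scanner surface over the control-point
#' aspect, at well-separated surface orientations (so together they
#' constrain all six rigid degrees of freedom), mirroring a user placing
#' rectangles over the operative region. Corner points are defined in the
#' scanner frame; spacing and size give roughly 1.3k jointly projected
#' nodes over the three rectangles.
#'
#' @param phantom A [synthetic_phantom()].
#' @param width,height Rectangle extents, mm.
#' @param offset_d Offset from the surface, mm.
#' @param spacing Grid step, mm.
#' @return List of corner/parameter specs consumable by [ersr_register()].
#' @export
default_hrpr_specs <- function(phantom, width = 30, height = 22, offset_d = 15,
                               spacing = 0.7) {
  stopifnot(inherits(phantom, "synthetic_phantom"))
  ctl <- landmark_coords(phantom$landmarks_truth, role = "control")
  ctr <- colMeans(phantom$truth_mesh$vertices)
  # three controls whose outward directions are maximally spread in angle:
  # the rays of the three rectangles then span three well-separated
  # directions, which is what lets the surface stage observe all three
  # translation components (each rectangle constrains motion along its
  # own ray) and gives rotation lever-arm diversity
  dirs <- sweep(ctl, 2L, ctr)
  dirs <- dirs / row_norms(dirs)
  cosd <- abs(dirs %*% t(dirs))  # |cos|: a ray and its opposite span the same line
  diag(cosd) <- 1
  pick <- as.integer(which(cosd == min(cosd), arr.ind = TRUE)[1L, ])
  pick <- c(pick, which.min(apply(cosd[pick, , drop = FALSE], 2L, max)))
  specs <- lapply(pick, function(i) {
    p <- ctl[i, ]
    n <- p - ctr
    n <- n / vnorm(n)  # outward radial direction approximates the normal
    u <- c(-n[2], n[1], 0)
    if (vnorm(u) < 1e-6) u <- c(1, 0, 0)
    u <- u - sum(u * n) * n
    u <- u / vnorm(u)
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3], n[1] * u[2] - n[2] * u[1])
    p1 <- p - (width / 2) * u - (height / 2) * v
    tr <- phantom$transforms$truth_to_scanner
    list(p1 = as.numeric(apply_transform(tr, p1)),
         p2 = as.numeric(apply_transform(tr, p1 + width * u)),
         p3 = as.numeric(apply_transform(tr, p1 + width * u + height * v)),
         offset_d = offset_d, spacing = spacing)
  })
  attr(specs, "anchor_controls") <- rownames(ctl)[pick]
  specs
}

#' Select the control points used for the study's mean TRE
#'
#' Registration accuracy in this design is assessed in the operative
#' region the projection rectangles cover, so the headline mean TRE is
#' computed over a small set of control points near the rectangles (the
#' phantom-study convention of averaging TRE over selected controls)
#' rather than over every control on the model, where the figure would
#' mostly measure extrapolation far outside the matched region.
#'
#' @param phantom A [synthetic_phantom()].
#' @param specs HRPR specs from [default_hrpr_specs()] (scanner frame).
#' @param n Number of controls (default 4).
#' @return Character vector of control names, nearest rectangle centres
#'   first.
#' @export
select_study_controls <- function(phantom, specs, n = 4) {
  ctl <- landmark_coords(phantom$landmarks_truth, role = "control")
  tr <- phantom$transforms$truth_to_scanner
  ctl_sc <- apply_transform(tr, ctl)
  centres <- t(vapply(specs, function(s)
    (as.numeric(s$p1) + as.numeric(s$p3)) / 2, numeric(3)))
  d <- vapply(seq_len(nrow(ctl_sc)), function(i)
    min(row_norms(sweep(centres, 2L, ctl_sc[i, ]))), numeric(1))
  rownames(ctl)[order(d)][seq_len(min(n, nrow(ctl)))]
}
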