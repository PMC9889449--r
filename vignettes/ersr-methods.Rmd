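---
title: "Equal-resolution surface registration: model, assumptions and design choices"
author: "ersr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equal-resolution surface registration: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ersr)
```

## The problem

Image-guided ("image to patient") surgery needs the rigid transform that
maps a preoperative CT-derived surface model into the coordinate frame in
which instruments are tracked. The classical solution is a paired-point
landmark transform (LTR): a least-squares rigid fit on a handful of named
fiducial markers measured in both frames. Its accuracy is limited by how
precisely those few markers can be localized, particularly on the
resolution-limited CT reconstruction.

Surface matching can correct a landmark pre-registration by aligning the
two surface models themselves, but a CT surface (in-plane pixels of
0.4-0.5 mm, slices of 1.5 mm) and a structured-light scanner surface
(~0.1 mm resolution) sample the same anatomy very differently, and
iterative closest point (ICP) between clouds of very different density and
with no usable correspondence is fragile. The equal-resolution surface
registration (ERSR) pipeline implemented here addresses that mismatch:

1. **Landmark transform** (`fit_landmark_transform()`): centroid
   subtraction and SVD of the cross-covariance, with the sign of the
   smallest singular direction flipped whenever the best orthogonal map
   would be a reflection. Mirror "registrations" -- a real failure mode
   when models still contain inner surfaces -- are therefore impossible by
   construction; every stored rotation has determinant +1.
2. **Equal-resolution surface matching**: the user places one or more
   offset rectangles (HRPR) over the operative region of the scanner
   model. Each rectangle carries a uniform grid that is ray-projected onto
   *both* meshes; only grid nodes that hit both surfaces are kept, in
   identical order. The two resulting clouds have the same cardinality and
   approximate index-wise correspondence regardless of the meshes' native
   resolutions. Point-to-point ICP between them (`icp_register()`)
   produces the surface correction `SR`.
3. **Reference-frame registration** (`register_to_drf()`): a second
   landmark fit maps the scanner frame onto pointer-palpated fiducials in
   the tracked dynamic reference frame (DRF).

The composed map `DRF ∘ SR ∘ LT` takes CT coordinates to tracker
coordinates. Accuracy is reported as FRE (residual at the fitted
fiducials), TRE (error at withheld control points) and, between the
registered surfaces, as nearest-point distance maps summarized by a
max-scaled histogram's first-bin frequency.

## Geometry conventions

* Units are millimetres; frames are right-handed; transforms act on
  column points, `p' = R p + t`; `compose_transforms(t2, t1)` applies `t1`
  first. On disk a transform is a row-major homogeneous 4x4 matrix with a
  self-describing `convention` field.
* An HRPR is built from three picked corners: the first edge fixes the
  in-plane `u` axis, the second is orthogonalized against it (picked
  corners are never exactly perpendicular). Which plane normal points away
  from the surface is resolved geometrically -- probe rays offset by `d`
  must return to the picked surface -- because a "clockwise corners"
  convention depends on the viewpoint.
* Grid nodes lie on the closed interval (both boundary rows included),
  row-major with the `u` index fastest; this ordering is what makes the
  two projected clouds index-correspondent.
* Ray casting keeps the intersection nearest the offset plane (smallest
  positive ray parameter, with a 1e-9 mm self-intersection guard). When a
  segmented model still contains an inner shell, this is the rule that
  selects the superficial (outer) surface, stated in a frame-independent
  way rather than in terms of any particular image axis.

## What the surface stage can and cannot correct

A point of honesty that shapes the whole evaluation design. Because both
clouds sample the *same* grid rays, each correspondence pair initially
differs only along its rectangle's ray direction. A rigid fit on such
pairs corrects the components of the landmark-transform error that project
onto the rectangle ray directions -- with three rectangles of well-spread
normals, essentially the full translation error -- but penalizes
tangential motion, so rotation errors (which slide the surface tangentially
almost everywhere on a near-convex bone) are corrected only through the
surface relief inside the rectangles, with a small gain per unit area.
Two design consequences:

* `default_hrpr_specs()` picks rectangle sites whose outward directions
  are maximally spread *as lines* (near-orthogonal, not near-antipodal),
  which makes all three translation components observable and maximizes
  rotational lever-arm diversity.
* Registration quality is assessed where the method is designed to
  deliver it: `select_study_controls()` returns the control points nearest
  the rectangles, mirroring the study convention of averaging TRE over
  selected controls in the operative region rather than over the whole
  model, where the figure would measure extrapolation.

ICP itself is plain point-to-point (`nearest_neighbors()` + rigid fit),
unidirectional, correspondences recomputed every iteration, stopping when
the matched RMS changes by less than `tol` (default 1e-6 mm) or at
`max_iter` (default 100). With full correspondences the matched RMS is
provably non-increasing, and the returned history lets callers verify it.
An optional `trim_fraction` discards the worst correspondences for
partial-overlap robustness; it is off by default and the monotonicity
guarantee applies only to the untrimmed variant. ICP is local: from a
grossly wrong initialization it converges, monotonically, to the wrong
optimum -- the landmark stage exists precisely to prevent that. The
projection is performed once, against the stage-1 alignment: experiments
with re-projecting after each ICP pass showed no reliable benefit (the
tangentially blind modes stay blind) and it complicates the transform
bookkeeping, so the simpler reading was kept.

## The synthetic phantom

`synthetic_phantom()` generates the full study fixture from one seed:

* **Truth surface**: an icosphere scaled to a ~200 mm ellipsoid (head-size
  field of view), modulated by 40 Gaussian bumps and indentations of
  5-15 % relative amplitude and 0.06-0.20 rad angular width. These
  amplitudes give local slopes up to ~1, comparable to facial-bone relief
  (orbital rims, nasal aperture) -- deliberately so, because surface
  matching on a near-ellipsoid is ill-posed (any rotation slides the
  surface within itself almost without cost). Generation verifies
  watertightness and rotational asymmetry (>1 mm RMS self-distance under
  30 degree rotations about each principal axis).
* **Landmarks**: five fiducials (M1-M5) spread over one aspect with
  >=20 mm pairwise spacing, twelve controls (C1-C12) elsewhere, all on
  mesh vertices.
* **CT degradation** (`degrade_to_ct()`): partial-volume occupancy
  (fraction of each voxel inside the surface, 0-255 scale, z-extents
  resolved analytically per sub-column) sampled at 0.39/0.43/0.47 mm
  pixels and 1.5 mm slices, then a 50 % isosurface. Intensity physics is
  not modelled; resolution is the only variable, as in the study design.
  The isosurface interpolates the occupancy fractions exactly as marching
  cubes on real CT interpolates partial-volume intensities, so surface
  error is far below the half-voxel worst case on smooth patches (~0.05 mm
  mean at resolution A) while slice quantization still dominates the
  z direction. Isosurfacing uses marching *tetrahedra* (six tetrahedra per
  cell around the 0-7 diagonal, shared-face diagonals consistent across
  cells): same quantization bound as table-driven marching cubes, no
  4096-entry case table to trust, roughly twice the triangles.
* **Observations**: CT-frame landmark picks are snapped to the nearest CT
  mesh vertex -- markers can only be localized on the resolution-limited
  reconstruction, which is what makes the landmark baseline resolution
  sensitive. Scanner landmarks get 0.05 mm isotropic noise (device
  accuracy; the scanner's native resolution is far below its mesh vertex
  spacing, so no snapping), palpation 0.25 mm (pointer accuracy), and
  manual pick imprecision is layered on with `perturb_landmark_picks()`
  (no published value; the paired studies here use 0.5 mm). Inter-frame
  poses are random rigid transforms (<=20 degrees, <=30 mm), recorded as
  ground truth.

What the phantom does **not** emulate: titanium-marker segmentation
artifacts (markers appearing to protrude above the CT surface), soft-tissue
deformation, CT beam physics, scanner occlusion and holes. A green test on
this fixture therefore establishes the geometric behaviour of the
algorithms under controlled noise -- not clinical accuracy.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| HRPR spacing | 0.7 | mm | grid step of the projected clouds; must be below the expected stage-1 misalignment so ICP correspondences can re-lock across nodes |
| HRPR size | 30 x 22 | mm | large enough to span surface relief; three such rectangles give ~4000 joint nodes |
| HRPR offset `d` | 15 | mm | clears the relief under the rectangle |
| ICP `tol` | 1e-6 | mm | matched-RMS change at which iteration stops |
| ICP `max_iter` | 100 | -- | typical convergence here is < 20 iterations |
| histogram `n_bins` | 11 | -- | a map with maximum 0.56 mm then has ~0.05 mm bins, matching the published worked example |
| CT pixels | 0.39/0.43/0.47 | mm | the three studied resolutions (A/B/C) |
| CT slice | 1.5 | mm | clinical slice thickness, fixed across resolutions |
| scanner noise | 0.05 | mm | device accuracy |
| palpation noise | 0.25 | mm | tracked-pointer accuracy |

## Numerical and degenerate-input choices

* Collinearity in `fit_landmark_transform()`: second singular value of the
  centred source below 1e-9 times the largest (rotation about the line is
  unobservable).
* `nearest_neighbors()` ties (exactly equal distances) resolve to the
  lowest target index; the kd-tree is contractually identical to
  exhaustive search and tested against it.
* An all-zero distance map yields a single degenerate histogram bin with
  frequency 1 (max-scaled binning would otherwise divide by zero).
* `distance_map()` defaults to nearest-vertex distances between dense
  point sets; `method = "triangle"` gives true point-to-surface distance
  (BVH-accelerated). `evaluate_registration()` defaults to the surface
  metric: reconstructed CT meshes have a vertex-sampling floor of one to
  several tenths of a millimetre that would otherwise swamp exactly the
  sub-0.1 mm structure the published distance maps resolve.
* Binary STL stores float32; expect ~1e-5 relative precision through that
  route. PLY support is ASCII only. Pipeline configs are JSON (this build
  carries no YAML dependency).

## Known limitations

* Rotation components of a landmark error are corrected only weakly by
  the surface stage on near-convex anatomy (see above); the implementation
  reproduces the *direction* of the published ERSR-versus-LTR comparisons,
  not their magnitudes, which depended on marker-segmentation biases that
  the surface stage is particularly good at removing and that this fixture
  deliberately does not model.
* Point-to-point ICP between two samplings of the same smooth surface has
  lattice-registry local minima; the grid spacing bounds the attainable
  correction. Spacing well below the expected stage-1 error is the
  mitigation.
* The TRE reported by `registration_error()` between two *observed*
  landmark sets contains the localization noise of both observations; with
  0.5 mm picks on both datasets its floor is ~1.1 mm even for a perfect
  transform. Ground-truth transform error on the synthetic fixture is the
  cleaner diagnostic and is what the recovery tests assert.
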