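# ersr — equal-resolution surface registration for image-guided surgery

Rigid "image to patient" registration of triangle-mesh surfaces, for
evaluating computer-aided-surgery registration pipelines. A preoperative
CT-derived bone model must be mapped into the coordinate frame in which
surgical instruments are tracked; the classical paired-point landmark
transform (**LTR**) is limited by how well a few fiducial markers can be
localized, especially on a low-resolution CT reconstruction. The
equal-resolution surface registration pipeline (**ERSR**) implemented here
corrects that landmark fit by surface matching on two point clouds that
are *constructed* to have equal resolution and approximate correspondence.

The three stages, with `R` a rotation, `t` a translation, `p' = R p + t`:

1. **LT** — least-squares rigid fit on paired fiducials (centroid
   subtraction + SVD of the cross-covariance, determinant sign corrected
   so a reflection is never returned):
   `LT = argmin_T Σᵢ ‖T(srcᵢ) − dstᵢ‖²`.
2. **SR** — the user places offset rectangles (HRPR: three picked corner
   points, offset distance `d`, grid step) over the operative region; each
   rectangle's uniform grid is ray-cast along `−normal` onto *both* the
   LT-aligned CT mesh and the scanner mesh, keeping the intersection
   nearest the plane and only the grid nodes that hit both surfaces. The
   two clouds (equal cardinality, index-correspondent) are aligned by
   point-to-point iterative closest point.
3. **DRF** — a second landmark fit onto pointer-palpated fiducials maps
   everything into the tracked dynamic-reference-frame coordinates.

`DRF ∘ SR ∘ LT` is the composed CT-to-tracker mapping. Evaluation tools:
fiducial/target registration error reports (FRE / TRE, with per-point,
mean ± sd and RMS values), fiducial localization error, nearest-point
distance maps between the registered surfaces, max-scaled histograms with
the **first-bin frequency** summary (bins span `[0, max]`, 11 by default,
so a 0.56 mm map gets ~0.05 mm bins), and Hausdorff distance.

A seeded synthetic phantom generator (`synthetic_phantom()`) reproduces
the whole study design in code: a ~200 mm bone-like surface with named
fiducials (M1–M5) and controls (C1–C12), CT degradation by partial-volume
voxelization (0.39 / 0.43 / 0.47 mm pixels, 1.5 mm slices) and isosurface
re-extraction, a noisy scanner-frame copy (0.05 mm), palpated landmarks in
a DRF frame (0.25 mm), and all ground-truth inter-frame transforms.

## Worked example

A small self-contained study: generate a phantom, add 0.5 mm manual
landmark-pick noise, register with both methods, and compare.

```r
library(ersr)

phantom <- synthetic_phantom(seed = 42, resolutions = c(A = 0.39), size = 120,
                             subdivisions = 4)
hrprs <- default_hrpr_specs(phantom)
dicom_lm   <- perturb_landmark_picks(phantom$dicom_landmarks$A, seed = 43, sigma = 0.5)
scanner_lm <- perturb_landmark_picks(phantom$scanner_landmarks,  seed = 44, sigma = 0.5)

res <- ersr_register(phantom$ct_meshes$A, phantom$scanner_mesh, dicom_lm, scanner_lm,
                     hrprs, palpated_landmarks = phantom$palpated_landmarks)
res
#> registration_result [ERSR]
#>   FRE: mean 0.9819 mm (rms 1.0224)
#>   TRE: mean 1.2584 +/- 0.5960 mm (rms 1.3817)
#>   TRE after DRF stage: mean 1.0268 mm
#>   ICP: 8 iterations, final cloud RMS 0.2710 mm

baseline <- ltr_register(dicom_lm, scanner_lm)
ev  <- evaluate_registration(phantom$ct_meshes$A, phantom$scanner_mesh,
                             compose_transforms(res$sr, res$lt))
evb <- evaluate_registration(phantom$ct_meshes$A, phantom$scanner_mesh,
                             baseline$composed_dicom_to_drf)
sprintf("first-bin frequency: ERSR %.2f vs LTR %.2f",
        ev$histogram$first_bin_frequency, evb$histogram$first_bin_frequency)
#> [1] "first-bin frequency: ERSR 0.32 vs LTR 0.14"
```

Reading the numbers: the FRE (~1 mm) is the residual at the five fitted
fiducials and mostly reflects the injected 0.5 mm pick noise on both
datasets; the TRE is measured at withheld control points and contains the
same observation-noise floor, so differences *between* methods matter more
than absolute values. The ICP cloud RMS (~0.27 mm) is the remaining
mismatch of the two projected grids, dominated by CT quantization. The
first-bin frequency — the fraction of surface points within one bin width
of the other registered surface — is the map-level summary: higher is
better, and the surface-matched result beats the landmark-only baseline.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch at the given
seed: it generates the full-size synthetic phantom at CT resolution A,
applies 0.5 mm landmark-pick noise, runs both ERSR and the LTR baseline
including the DRF stage, prints their FRE / TRE / distance-map summaries,
and writes the machine-readable report to `--out`.

## Layout

- `R/`, `src/` — implementation (R front end, Rcpp BVH ray casting,
  kd-tree search, voxelization and isosurfacing kernels)
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles
- `vignettes/ersr-methods.Rmd` — model, assumptions, parameter choices,
  what the synthetic phantom does and does not emulate
- `scripts/acceptance.R` — end-to-end run described above
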