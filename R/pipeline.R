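# The three-stage registration pipeline and its landmark-only baseline.

#' Full equal-resolution surface registration (ERSR)
#'
#' Stage 1 fits the landmark transform `LT` from the DICOM-frame
#' fiducials to the scanner-frame fiducials. Stage 2 projects the HRPR
#' grids onto the LT-moved DICOM mesh and onto the scanner mesh
#' ([project_pair()]) and refines the alignment with ICP from the
#' DICOM-projected to the scanner-projected cloud, giving the surface
#' correction `SR` (applied after `LT`, in scanner space). Stage 3, when
#' palpated landmarks are supplied, fits the `DRF` transform from the
#' scanner fiducials to their palpated positions.
#'
#' Projection happens once, against the stage-1 alignment; ICP then
#' operates purely on the two projected clouds.
#'
#' Error reports: `fre` on fiducials and `tre` on control points, both
#' between the DICOM and scanner observations under `compose(SR, LT)`
#' (i.e. before the DRF stage); `tre_drf` additionally compares DICOM
#' controls mapped all the way into the DRF frame against their palpated
#' positions, when those exist.
#'
#' @param dicom_mesh CT-derived [triangle_mesh()] (DICOM frame).
#' @param scanner_mesh Scanner-derived [triangle_mesh()] (scanner frame).
#' @param dicom_landmarks,scanner_landmarks [landmark_set()]s with
#'   matching fiducial names.
#' @param hrprs HRPR specifications: a list of `list(p1, p2, p3,
#'   offset_d, spacing)` (corners in the scanner frame, where the user
#'   places rectangles on the high-resolution model), or ready-made
#'   [build_hrpr()] objects.
#' @param palpated_landmarks Optional [landmark_set()] in the DRF frame.
#' @param icp_params List of [icp_register()] arguments
#'   (`max_iter`, `tol`, `trim_fraction`).
#' @param min_points Minimum jointly projected nodes ([project_pair()]).
#' @return Object of class `registration_result` with fields `lt`, `sr`,
#'   `drf`, `composed_dicom_to_drf`, `fre`, `tre`, `tre_drf`, `icp`,
#'   `clouds`, `method = "ERSR"`.
#' @export
ersr_register <- function(dicom_mesh, scanner_mesh, dicom_landmarks, scanner_landmarks,
                          hrprs, palpated_landmarks = NULL, icp_params = list(),
                          min_points = 100) {
  stopifnot(inherits(dicom_mesh, "triangle_mesh"), inherits(scanner_mesh, "triangle_mesh"))
  fid <- matched_fiducials(dicom_landmarks, scanner_landmarks)
  lt <- fit_landmark_transform(fid$src, fid$dst)
  hrprs <- resolve_hrprs(hrprs, scanner_mesh)
  pp <- project_pair(hrprs, dicom_mesh, scanner_mesh, min_points = min_points,
                     transform_a = lt)
  icp <- do.call(icp_register, c(list(src = pp$cloud_a, dst = pp$cloud_b), icp_params))
  sr <- icp$transform
  finish_registration("ERSR", lt, sr, dicom_landmarks, scanner_landmarks,
                      palpated_landmarks, icp = icp, clouds = pp)
}

#' Landmark-transform-only registration (LTR baseline)
#'
#' Binds only the first and third pipeline stages: the landmark transform
#' on fiducials and (optionally) the DRF registration, with no surface
#' matching (`sr` is the identity).
#'
#' @inheritParams ersr_register
#' @return A `registration_result` with `method = "LTR"` and `sr` the
#'   identity transform.
#' @export
ltr_register <- function(dicom_landmarks, scanner_landmarks, palpated_landmarks = NULL) {
  fid <- matched_fiducials(dicom_landmarks, scanner_landmarks)
  lt <- fit_landmark_transform(fid$src, fid$dst)
  finish_registration("LTR", lt, identity_transform(), dicom_landmarks, scanner_landmarks,
                      palpated_landmarks, icp = NULL, clouds = NULL)
}

#' Register the scanner frame to the dynamic reference frame
#'
#' Landmark transform from fiducials measured in the scanner frame to the
#' same fiducials palpated with a tracked pointer (DRF frame). Applied to
#' both datasets downstream, it brings image and scan into the frame in
#' which instruments are tracked.
#'
#' @param scanner_landmarks,palpated_landmarks [landmark_set()]s sharing
#'   at least three fiducial names.
#' @return A [rigid_transform()] scanner -> DRF.
#' @export
register_to_drf <- function(scanner_landmarks, palpated_landmarks) {
  fid <- matched_fiducials(scanner_landmarks, palpated_landmarks)
  fit_landmark_transform(fid$src, fid$dst)
}

resolve_hrprs <- function(hrprs, mesh) {
  if (inherits(hrprs, "hrpr")) return(list(hrprs))
  stopifnot(is.list(hrprs), length(hrprs) >= 1L)
  lapply(hrprs, function(h) {
    if (inherits(h, "hrpr")) return(h)
    build_hrpr(h$p1, h$p2, h$p3, h$offset_d, h$spacing, mesh)
  })
}

finish_registration <- function(method, lt, sr, dicom_landmarks, scanner_landmarks,
                                palpated_landmarks, icp, clouds) {
  sr_lt <- compose_transforms(sr, lt)
  shared_fid <- intersect(dicom_landmarks$names[dicom_landmarks$roles == "fiducial"],
                          scanner_landmarks$names[scanner_landmarks$roles == "fiducial"])
  shared_ctl <- intersect(dicom_landmarks$names[dicom_landmarks$roles == "control"],
                          scanner_landmarks$names[scanner_landmarks$roles == "control"])
  fre <- registration_error(landmark_coords(dicom_landmarks, names = shared_fid),
                            landmark_coords(scanner_landmarks, names = shared_fid), sr_lt)
  tre <- if (length(shared_ctl))
    registration_error(landmark_coords(dicom_landmarks, names = shared_ctl),
                       landmark_coords(scanner_landmarks, names = shared_ctl), sr_lt)
  drf <- NULL
  tre_drf <- NULL
  composed <- sr_lt
  if (!is.null(palpated_landmarks)) {
    drf <- register_to_drf(scanner_landmarks, palpated_landmarks)
    composed <- compose_transforms(drf, sr_lt)
    ctl_drf <- intersect(shared_ctl,
                         palpated_landmarks$names[palpated_landmarks$roles == "control"])
    if (length(ctl_drf))
      tre_drf <- registration_error(landmark_coords(dicom_landmarks, names = ctl_drf),
                                    landmark_coords(palpated_landmarks, names = ctl_drf),
                                    composed)
  }
  structure(list(method = method, lt = lt, sr = sr, drf = drf,
                 composed_dicom_to_drf = composed, fre = fre, tre = tre,
                 tre_drf = tre_drf, icp = icp, clouds = clouds),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]\n", x$method))
  cat(sprintf("  FRE: mean %.4f mm (rms %.4f)\n", x$fre$mean, x$fre$rms))
  if (!is.null(x$tre))
    cat(sprintf("  TRE: mean %.4f +/- %.4f mm (rms %.4f)\n", x$tre$mean,
                if (is.na(x$tre$sd)) 0 else x$tre$sd, x$tre$rms))
  if (!is.null(x$tre_drf))
    cat(sprintf("  TRE after DRF stage: mean %.4f mm\n", x$tre_drf$mean))
  if (!is.null(x$icp))
    cat(sprintf("  ICP: %d iterations, final cloud RMS %.4f mm\n", x$icp$iterations,
                x$icp$rms_history[length(x$icp$rms_history)]))
  invisible(x)
}
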