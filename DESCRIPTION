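Package: ersr
Title: Equal-Resolution Surface Registration for Image-Guided Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid image-to-patient registration of triangle-mesh surfaces for
    computer-aided surgery. Implements the equal-resolution surface registration
    (ERSR) pipeline: paired-point landmark (fiducial) fitting, projection of
    user-defined high-resolution offset rectangles (HRPR) onto a CT-derived and a
    surface-scanner-derived mesh to obtain two equal-resolution, approximately
    corresponding point clouds, iterative closest point refinement, and a final
    landmark registration into a tracked dynamic reference frame. Ships the
    evaluation toolkit used to benchmark such registrations (fiducial/target
    registration error, nearest-point distance maps, max-scaled histograms with
    first-bin frequency, Hausdorff distance) and a seeded synthetic skull-phantom
    generator that emulates the CT-versus-scanner study design, including CT
    resolution degradation by voxelization and isosurface re-extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
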