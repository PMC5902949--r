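Package: pcasim
Title: Phase-Contrast MR Angiography Simulation on Numerical Renal Arterial Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates phase-contrast magnetic resonance angiography (PCA),
    both conventional 2D/3D and echo-planar (EPI) accelerated, on numerical
    models of renal arterial trees.  Provides staged constrained-constructive
    growth of synthetic vascular trees under matter preservation, Poiseuille's
    law and the bifurcation law; an analytic laminar Poiseuille-network flow
    solution with streamline tracing and incompressibility-preserving spin
    isochromat seeding; analytic Bloch-equation signal simulation under full
    sequence waveforms with bipolar velocity-encoding gradients; Cartesian
    k-space reconstruction to phase-difference velocity maps; ground-truth
    error quantification via K-nearest-neighbour estimates, Bland-Altman and
    linear agreement statistics; and a vessel segmentation chain (multi-scale
    Hessian vesselness, flood fill, 3D skeletonization, centerline smoothing
    and covariance-based radius estimation) for closing the loop from tree to
    synthetic CT volume and back to recovered geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
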