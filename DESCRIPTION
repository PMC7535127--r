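Package: fibroRD
Title: Fibrosis-Guided Mapping of Re-Entrant Driver Locations in Atrial Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based computational workflow for locating re-entrant
    drivers (RDs) of atrial fibrillation relative to atrial fibrosis.
    Provides a monodomain reaction-diffusion solver with a three-current
    atrial Fenton-Karma cell model on voxelized left-atrial geometries,
    image-intensity-ratio (IIR) fibrosis segmentation with interpolated
    diffusion slowing, phase-singularity tip tracking, tip-probability
    target-area (TA) mapping, and virtual catheter ablation with
    mean-frequency outcome analysis. A synthetic-data module generates
    left-atrium-like shell geometries and LGE-like intensity volumes with
    controlled fibrosis burden so every stage is testable without patient
    imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    igraph,
    clue
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
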