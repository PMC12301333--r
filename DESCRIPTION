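Package: petdix
Title: PET Lesion Dissemination Indices and Their Prognostic Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes tumour dissemination indices from 3D FDG-PET volumes in
    SUV units: metabolic tumour volume (MTV), centroid-based distances (Dmax,
    Dmax_bulk, SPREAD_bulk, SPREAD_patient), the outermost-voxel distance
    Dmax_Vox, and its 2D surrogate Dmax_VoxMIP measured on a coronal
    maximum-intensity projection. Includes adaptive SUV-threshold (Nestle)
    lesion segmentation, ingestion of external label masks, synthetic PET
    phantoms and simulated survival cohorts for validation, and the survival
    toolchain used to assess prognostic value: Contal-O'Quigley optimal
    cutpoints with Brownian-bridge adjusted p-values, Kaplan-Meier rates, Cox
    hazard ratios, added-variable Wald tests over IPI, cross-classified risk
    groups, and Bland-Altman agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    RNifti,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
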