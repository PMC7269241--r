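Package: mracpet
Title: Simulated Impact of MR-Based Attenuation-Correction Error on
    Automated FDG-PET Alzheimer Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulation pipeline for studying how voxel-wise errors from
    atlas-based MR attenuation correction (MRAC) of brain FDG-PET propagate
    into an automated Alzheimer's-discrimination score. Provides a synthetic
    template-space phantom cohort generator with an age-regressed normal
    reference database, multiplicative MRAC-like error fields with
    calibrated regional statistics, FWHM-specified Gaussian smoothing,
    affine registration and trilinear resampling, a PALZ-style scoring
    chain (intensity normalization to an AD-preserved mask, voxel-wise
    age-regression t-statistics, AD t-sum, PET score), the error-map cross
    simulation, and diagnostic-accuracy evaluation at fixed PET-score
    cutoffs with Wilson confidence intervals, error-map ranking,
    Bland-Altman agreement and between-institution comparison.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
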