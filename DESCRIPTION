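Package: petsuvr
Title: Reference-Tissue Kinetic Modeling and Static-Window SUVR Validation for Preclinical Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying radiotracer binding in small-animal brain
    PET without arterial sampling: simplified reference tissue model (SRTM)
    fitting by the basis-function method with optional nonlinear refinement,
    reference Logan graphical analysis, standardized uptake value ratio
    (SUVR) computation over static imaging windows with SUVR-versus-DVR
    agreement analysis and optimal-window selection, genotype group
    comparison, and exact noncentral-t power and sample-size analysis.
    Includes a one-tissue-compartment simulator of regional time-activity
    curves with a realistic PET frame-noise model for building synthetic
    two-genotype cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    RNifti,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
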