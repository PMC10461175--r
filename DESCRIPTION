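Package: fflmpi
Title: Field-Free-Line Magnetic Particle Imaging Simulation and
    Functional Time-Series Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for functional magnetic
    particle imaging (fMPI) of cerebral blood volume with a mechanically
    rotating field-free-line (FFL) scanner. Provides a Langevin-physics
    projection simulator with harmonic-resolved sinograms, synthetic
    dilution and brain phantoms with hypercapnia block physiology and a
    two-component (thermal plus signal-proportional) noise model,
    forward-model image reconstruction by truncated-SVD pseudoinverse
    with a low-spatial-frequency singular-vector selection rule,
    band-stop preprocessing for half-rotation gain artifacts, a
    five-regressor general linear model with a CO2 response function and
    tracer-decay term, and sensitivity metrics (Rician-corrected SNR,
    dilution-series linearity, detection limits, noise-model fits and
    voxel iron accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
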