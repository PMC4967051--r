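Package: fractalmet
Title: Fractal and Multifractal Quantification of Metastatic Lesion Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial dispersion of tracer-avid lesions in 3D
    whole-body emission-tomography volumes using box-counting fractal
    dimensions, the generalized (Renyi) dimension spectrum D_q, and an
    averaged multifractal index for serial-study comparison. Includes a
    kinetic Monte Carlo model of metastatic spread, in which malignant cells
    perform random walks on a deterministic fractal vascular lattice and
    stochastically colonize adjacent tissue, together with a power-law times
    exponential growth-law fit for the number of colonized sites over time,
    a synthetic phantom generator, NIfTI and basic DICOM-series input, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
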