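Package: phantomspec
Title: Diffuse Reflectance and Fluorescence Modelling for Tissue-Mimicking Optical Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of diffuse reflectance and
    fluorescence spectroscopy in homogeneous turbid media, aimed at liquid
    optical phantoms built from a haemoglobin-like absorber, polystyrene
    microsphere scatterers and fluorophores. Provides Mie theory for
    microsphere suspensions, Monte Carlo photon transport in a slab,
    albedo-scaling reconstruction of diffuse reflectance with least-squares
    extraction of absorption and reduced scattering coefficients, sparse
    spectral-band sampling with cubic-spline reconstruction, photon-migration
    extraction of intrinsic fluorescence from bulk fluorescence, non-negative
    spectral unmixing of fluorophores, and a synthetic-phantom generator with
    known ground truth for validating the whole chain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
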