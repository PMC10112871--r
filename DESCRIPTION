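Package: opsinshift
Title: Spectral Sensitivity Decomposition and Parallel Opsin Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two linked analyses of insect visual-pigment tuning
    across diurnal-nocturnal transitions. The first decomposes
    electroretinogram (ERG) derived spectral sensitivities into
    ultraviolet-, short- and long-wavelength visual-pigment absorbance
    templates (alpha plus beta bands) to estimate peak wavelengths
    (lambda_max) and pigment contributions, with optional screening-pigment
    filtering, after inverting the Naka-Rushton intensity-response function.
    The second reconstructs ancestral amino-acid states of opsin alignments
    on a labelled species tree under the JTT model (optionally with
    gamma-distributed rates), identifies parallel substitutions on
    independently evolved diurnal lineages, and tests their excess over the
    neutral Poisson expectation. Synthetic-data generators for both
    pipelines support simulation studies and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
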