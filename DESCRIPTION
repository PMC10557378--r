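Package: pgms3
Title: Prostaglandin Isomer Differentiation and Imaging from Silver-Adduct
    MS3 Product-Ion Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes the prostaglandin isomers PGE2, PGD2 and
    delta12-PGD2 (all C20H32O5) from silver-cationized tandem mass
    spectrometry. Provides exact-mass arithmetic for [M+107Ag]+ adducts
    and neutral-loss assignment of MS2/MS3 product ions; extraction of
    the three diagnostic MS3 channels (m/z 331, 333, 341) from centroided
    mzML; a polynomial calibration model (quadratic surface plus cubic
    calibration curve with numeric inversion and closure to 100 percent)
    with hold-out cross-validation; pixel-grid assembly, internal-standard
    quantitation, masking and signal-to-noise filtering for mass
    spectrometry imaging; and a seedable forward-model simulator of
    calibration mixtures and imaging phantoms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    mzR,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
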