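Package: pcisr
Title: Postcolumn Infused Standard Correction for Targeted LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting ionization matrix effects in targeted
    LC-MS/MS (MRM/SRM) assays with a postcolumn infused standard (PCIS).
    Reads MRM chromatograms from mzML or delimited trace tables, resamples
    and smooths them, corrects analyte signals by the scan-by-scan ratio to
    the PCIS signal, and integrates peaks by a height-fraction rule. Includes
    the design-phase analyses (suppression-profile correlation and PCIS
    grouping, PCIS concentration optimization with an LLOQ rule), three
    correction-performance evaluation methods (matrix-effect and precision
    across matrices, concentration-factor series, dilution linearity), and
    calibration-curve parallelism assessment with slope-difference verdicts.
    A synthetic chromatogram simulator with known ground truth exercises
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mzR,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
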