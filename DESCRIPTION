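Package: respectra
Title: Intensity-Prediction-Assisted Rescoring of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying tryptic and non-tryptic (HLA ligand)
    peptides from tandem mass spectra with the help of predicted fragment-ion
    intensities. Provides b/y fragment annotation of MGF peak lists at ppm
    tolerance with masked, base-peak-normalized intensity tensors; a trainable
    recurrent encoder-decoder fragment-intensity predictor with normalized
    spectral-contrast-angle loss and collision-energy calibration; an additive
    retention-time model; feature-only semi-supervised target-decoy rescoring
    with PSM- and peptide-level q-values; a consecutive-filter re-assessment
    of proposed proteasomally spliced peptides against canonical competitors;
    position-weight-matrix motif scoring with Jensen-Shannon divergence; and a
    rule-based synthetic spectrum generator that serves as ground truth for
    every component.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
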