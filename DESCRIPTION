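Package: proteotier
Title: Tiered Quantifiable-Proteome Characterization for DIA-MS Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the analytical performance of data-independent
    acquisition mass spectrometry (DIA-MS) assays from long-format peptide
    quantification reports. Computes MS2 total-ion-current normalized
    intensities, intra-day and multi-day coefficients of variation under
    detection-count gates, dilution-curve linearity with lower limits of
    detection and quantification, and classifies every peptide and protein
    into nested observable, reliable, reproducible and quantifiable proteome
    tiers per biofluid and workflow. Includes a synthetic-report generator
    with ground-truth labels for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
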