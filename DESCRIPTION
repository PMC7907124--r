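Package: ramanomaly
Title: Anomaly Detection in Raman Hyperspectral Maps with Targeted
    Metabolomics Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing Raman micro-spectroscopy maps of tissue
    and targeted serum metabolite panels.  Implements polyline baseline
    correction, substrate-pixel removal, band cropping and mean spectra;
    a one-class support-vector-machine anomaly detector operating on PCA
    scores of physiological reference spectra with per-pixel anomaly
    confidence maps and connected anomaly regions; Raman-band to
    metabolite assignment against a built-in fingerprint library; and
    fold-change plus paired t-test differential analysis of targeted
    metabolite panels with volcano and class summaries.  Includes
    synthetic-data generators with known ground truth (planted lesions,
    substrate pixels, metabolite effects) so every stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
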