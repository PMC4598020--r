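Package: chamberflux
Title: Closed-Chamber Respirometry Reduction for Benthic Calcifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces start/end water-chemistry samples from sealed in situ
    incubation chambers to control-corrected coral metabolic rates:
    calcification by the total-alkalinity anomaly method, net photosynthesis
    and dark respiration from dissolved-oxygen fluxes, gross photosynthesis,
    and their daily integrals. Includes a chamber-volume safety analysis
    (supersaturation/anoxia classification, replicate consensus, and a
    volume acceptance rule), a water-extraction error budget, paired and
    independent chamber-equivalence tests, restricted-maximum-likelihood
    mixed models for species-by-habitat comparisons, and a forward simulator
    of chamber incubations so every stage of the pipeline can be validated
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    nlme,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
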