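Package: cralekit
Title: Quantitative Analysis of CPR-Associated Lung Edema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal quantification of cardiopulmonary-resuscitation-
    associated lung edema (CRALE): quantitative lung CT densitometry
    (Hounsfield-unit aeration compartments, lung weight and gas volume,
    gravitational density gradient, ten-slice whole-lung extrapolation),
    partitioned respiratory mechanics from airway and esophageal pressure
    traces (occlusion validation, per-compression esophageal pressure
    swings, lung and chest-wall compliance and driving pressure), oxygen
    transport physiology (oxygen contents, delivery, uptake, Berggren
    venous-admixture shunt), and point-counting stereology on histology
    class maps. Includes seeded synthetic-data generators (CT phantoms,
    CPR pressure waveforms, blood-gas panels, histology label images,
    multi-animal cohorts) with exact ground truth so every analysis stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
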