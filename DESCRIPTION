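Package: afmpore
Title: Pore-Size Classification of Nanoporous Membranes from AFM
    Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Statistical pipeline for classifying nanoporous
    regenerated-cellulose dialysis membranes by molecular-weight cutoff
    (MWCO) from atomic force microscopy (AFM) pore-radius measurements.
    Provides moment-based normality screening with Monte-Carlo
    Jarque-Bera critical values, Gamma fitting and parametric-bootstrap
    replication, hold-out logistic classification with ROC/AUC and
    Youden-index analysis, test-size optimization for scan-time
    reduction, instrument-drift and environmental-shift quality control,
    and physical reference models (theoretical Stokes radius,
    measurement-accuracy errors, hydrogel swelling adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    stats,
    utils
Suggests:
    fitdistrplus,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
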