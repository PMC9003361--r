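Package: emgatrophy
Title: Surface Electromyography Analysis to Distinguish Causes of Muscular Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for distinguishing nerve-injury
    from limb-immobilization muscular atrophy using surface electromyography
    (sEMG). Provides generators for voluntary-contraction sEMG and electrically
    evoked compound muscle action potential trains with per-epoch ground truth,
    a 50 Hz notch plus 20-500 Hz Butterworth preprocessing chain, evoked-response
    parameter extraction (latency, amplitude, duration, area under the curve),
    windowed time- and frequency-domain feature extraction (RMS, iEMG, ARV,
    median and mean power frequency) with affected-versus-reference ratio
    normalization, and classification with gradient-boosted trees, RBF support
    vector machines and k-nearest neighbours, evaluated by stratified
    cross-validation with accuracy, specificity and sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    xgboost,
    class,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
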