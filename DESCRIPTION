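Package: painbci
Title: Closed-Loop Pain Detection from EEG and Skin Conductance
Version: 0.1.0
Authors@R:
    person("painbci", "developers", email = "painbci@example.org", role = c("aut", "cre"))
Description: Offline training and simulated real-time evaluation of a
    brain-computer interface that detects pain from multichannel EEG and
    skin-conductance recordings. Provides band-pass filtering, running
    observation window extraction with peak-to-peak artifact rejection,
    spectral and entropy EEG features, amplitude-based skin-conductance
    features, radial-kernel support vector machine decoders with
    stimulus-grouped cross-validation, a dual-modality fusion engine with
    intervention triggering, a synthetic-session generator emulating the
    experimental protocols, and the accompanying nonparametric feature
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    yaml,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
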