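Package: hepvalid
Title: Validation Tools for Heartbeat-Evoked Potential Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for separating genuine heartbeat-evoked potential (HEP)
    effects in EEG from heartbeat-independent confounds such as slow
    anticipatory potentials. Implements surrogate heartbeat null analysis
    (R-peak timing shuffles within condition), pseudotrial correction
    (subtraction of epochs locked to randomly inserted pseudo-R-peaks),
    spatio-temporal cluster-based permutation t-tests with max-statistic
    family-wise error control, Spearman correlation clusters for cardiac field
    artifact checks, TOST equivalence testing against a smallest effect size of
    interest, and a simulation framework (1/f background, coupled simulated
    ERP/HEP amplitudes, signal-to-noise calibration) for simulation-based power
    studies of the combined correction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
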