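Package: nerveaudit
Title: Validation Audits for Machine Learning on Hierarchical Neural Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing data leakage and over-optimism in machine
    learning evaluations on hierarchical neural and biomedical data, where
    instances are nested in sessions and subjects. Provides the standard
    family of data-splitting schemes (instance, group, time-blocked, segment
    and nested cross-validation) with structural guarantees, label
    randomization and permutation null controls, subject- and session-identity
    probes, a seed-deterministic reference multi-layer perceptron, analytic
    and empirical chance-level estimation, the corrected resampled t-test for
    fold-wise comparisons, a hierarchical synthetic-data generator with
    subject fingerprints and temporal autocorrelation, and an audit report
    with a machine-readable reporting checklist.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    rhdf5,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
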