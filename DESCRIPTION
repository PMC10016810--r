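Package: strokenet
Title: Virtual-Lesion Connectomics and Prediction of Post-Stroke Motor Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds patient lesion masks into healthy streamline tractography
    connectomes ("virtual lesioning"), computes weighted and binary whole-brain
    graph-connectivity measures with density-matched binarization, combines them
    with clinical benchmark features (age, initial Fugl-Meyer score, lesion
    volume, cortico-spinal tract asymmetry), and predicts upper-limb motor
    recovery with VIF-selected ridge regression under nested leave-one-out
    cross-validation. Includes fitter/non-fitter classification against the
    proportional recovery rule, bootstrap confidence intervals, rank-based
    univariate statistics, and a synthetic phantom-brain module that generates
    parcellations, tractograms, lesions and patient cohorts so the entire
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
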