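Package: coroflow
Title: Virtual Fractional Flow Reserve on Coronary Vessel Graphs with a
    One-Dimensional Haemodynamic Model
Version: 0.1.0
Authors@R:
    person("Coroflow", "Developers", email = "coroflow@example.org",
           role = c("aut", "cre"))
Description: Tools for noninvasive estimation of the fractional flow
    reserve (FFR) of coronary artery stenoses. The package extracts a
    coronary vessel graph from contrast-enhanced volumetric images
    (here: synthetic phantoms emulating coronary CT angiography),
    personalizes a one-dimensional unsteady blood-flow model on that
    graph from routine patient data, computes virtual FFR at marked
    stenosis sites under simulated hyperemia, and evaluates diagnostic
    concordance against a reference standard with Wilson score
    intervals, ROC/AUC, Bland-Altman agreement and Spearman rank
    correlation. Synthetic generators for coronary trees, voxel
    phantoms and paired virtual/invasive cohorts support end-to-end
    testing without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
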