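Package: hotspotpet
Title: Hotspot Geometry Biomarkers and Recurrence Statistics from PET Images
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes normalized hotspot-to-centroid (NHOCmax) and
    hotspot-to-perimeter (NHOPmax) distances, together with conventional
    metabolic parameters (SUVmax, SUVmean, MTV, TLG), from 3D PET SUV
    volumes. Provides threshold-based metabolic tumor segmentation with
    perimeter extraction, isotropic resampling, synthetic tumor phantoms
    with analytic ground truth, simulated patient cohorts, and the
    downstream recurrence-prediction statistics (Spearman correlations,
    ROC with Youden cut-off, logistic regression, Cox proportional
    hazards, Kaplan-Meier with log-rank test). Includes a minimal NIfTI-1
    reader/writer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
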