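Package: bsaecho
Title: Body Surface Area Estimation and Echocardiographic Indexing in Athletes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing body surface area (BSA) predictive equations
    against criterion BSA derived from triangulated 3D body-scan meshes, and
    for assessing the downstream impact of the chosen BSA normalization on
    echocardiographic relative indexes and ventricular-dilatation prevalence.
    Implements a registry of ten literature BSA equations with strict unit
    conventions, mesh surface-area computation from OBJ/PLY scans with
    replicate averaging and Grubbs outlier QC, method-comparison statistics
    (Pearson correlation, RMSE, relative bias, Bland-Altman limits of
    agreement, Friedman omnibus testing), sex-specific dilatation
    classification with an athlete's-heart exclusion rule and McNemar paired
    comparisons of prevalence, and a fully seeded synthetic-cohort generator
    for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
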