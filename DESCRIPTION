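Package: crypttags
Title: Colon Crypt Stem Cell Dynamics from Bisulfite Amplicon Methylation Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers colon crypt stem cell dynamics from barcoded bisulfite
    amplicon sequencing of an unexpressed CpG island. Processes raw reads
    (demultiplexing, bisulfite-aware global alignment to an in-silico
    converted reference, conversion-control and coverage filtering, per-read
    CpG genotyping) into per-crypt methylation-tag tables; applies an error
    frequency cutoff and computes tag diversity and percent methylation per
    crypt; fits mixed-effects negative binomial and linear regressions of
    crypt-level outcomes on treatment and time with patient-level random
    intercepts; and provides a stem-cell niche simulator (Moran-type neutral
    drift with per-division methylation errors plus an assay noise layer)
    that generates fully synthetic cohorts with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    MASS,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
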