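Package: progstrat
Title: Two-Stage Clinicopathologic and Gene-Expression Survival
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-stage prognosis modelling for surgical cancer cohorts,
    as used in hepatocellular carcinoma studies. Stage one selects
    significant clinicopathologic parameters by univariate Cox screening,
    combines them in a multivariate Cox classifier and dichotomizes
    patients into good and poor prognosis groups on a leave-one-out
    linear predictor. Stage two, within each stratum, runs a
    leakage-safe nested leave-one-out gene-expression predictor: per-fold
    univariate Cox gene screening, top-K selection, principal-component
    compression, a Cox model on the top components and projection of the
    held-out patient. Also provides robust (Tukey bisquare) age/sex
    residualization of expression traits, hypergeometric gene-signature
    overlap enrichment, a cis-eQTL scan with Benjamini-Hochberg false
    discovery control, outcome-associated SNP (cSNP) scans adjusted for
    clinicopathology, eSNP-in-cSNP enrichment with a randomized-endpoint
    permutation null, and a synthetic-cohort generator with planted
    truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
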