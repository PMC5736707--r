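Package: clonedyn
Title: Longitudinal Subclonal Reconstruction and Clonal Kinetics from Serial
    Tumor Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking subclonal dynamics in serially sampled
    tumors, motivated by chronic lymphocytic leukemia under targeted
    therapy. Converts force-called somatic read counts to cancer cell
    fraction (CCF) posteriors given sample purity and local copy number,
    clusters mutations jointly across timepoints with a Dirichlet-process
    mixture sampled by MCMC, tests for significant early clonal shifts
    with cohort-wide false-discovery control, enumerates phylogenies under
    pigeonhole and sibling-sum constraints, infers per-clone exponential
    growth rates by a mutation-reassignment MCMC with back-extrapolation
    of clone sizes to treatment initiation, and provides cohort-level
    association statistics (Fisher exact, Kaplan-Meier, log-rank). A
    synthetic-cohort generator with known ground truth supports end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
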