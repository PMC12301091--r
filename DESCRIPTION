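Package: phemr
Title: Phenome-Wide Mendelian Randomization with Matched-SNP Enrichment
    and Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical chain for linking one disease's GWAS risk loci to
    other phenotypes: covariate-matched control-SNP selection and Fisher
    exact PheWAS enrichment with false-discovery-rate correction,
    phenome-wide and bidirectional two-sample Mendelian randomization
    (inverse-variance weighted, MR-Egger, weighted median and weighted
    mode, with heterogeneity and pleiotropy diagnostics), and Bayesian
    colocalization of regional summary statistics via Wakefield
    approximate Bayes factors. Includes a synthetic summary-statistics
    generator with known ground truth so every stage is testable without
    biobank downloads, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
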