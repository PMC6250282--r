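Package: frailtyomics
Title: Multi-Omics Twin Analysis of Frailty and Chronic Widespread Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multi-omics studies of the
    deficit-accumulation Frailty Index (FI) and chronic widespread pain (CWP)
    in female twin cohorts. Provides a seeded synthetic-cohort generator with
    monozygotic/dizygotic twin structure, Rockwood-style Frailty Index
    construction with twin-pair discordance ranking, maximum-likelihood ACE
    variance decomposition including a liability-threshold model for
    dichotomous traits and a bivariate continuous-binary genetic-correlation
    fit, metabolite normalization and association scans with false discovery
    rate control and family-adjusted multivariable selection, SNP quality
    control and additive genome scans, a discordant-twin epigenome-wide
    association design with Fisher p-value combination and nearest-gene
    assignment, gene-set overrepresentation testing, two-stage path analysis
    of direct and CWP-mediated effects, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    MASS,
    optparse
Config/testthat/edition: 3
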