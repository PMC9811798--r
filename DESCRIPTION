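Package: owc
Title: Omnibus Weighted Combination Tests for Gene-Based Association
    from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association testing from genome-wide association
    study (GWAS) summary statistics. Implements the omnibus weighted
    combination (OWC) test, which combines the burden statistic, the
    minor-allele-frequency weighted sum statistic, a maximized score
    statistic and the sum of squared Z-scores through a grid search over
    simplex weights, with the minimum p-value calibrated by Monte Carlo
    sampling from the multivariate normal null implied by the linkage
    disequilibrium (LD) matrix. Also provides the classical comparison
    tests (sum test, squared sum test, adaptive test, adaptive sum of
    powered score tests, GATES), LD-matrix utilities (estimation from
    dosages, positive semi-definite repair, Cholesky factorization,
    regularized inversion), summary-statistic input with quality-control
    filtering (minor allele frequency and LD pruning), and a simulation
    harness for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
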