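Package: mvqtlsim
Title: Power Comparison of Multivariate GWAS Tests by Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for comparing the power of multivariate
    genome-wide association tests on a single quantitative trait locus.
    Simulates a bi-allelic QTL in Hardy-Weinberg equilibrium together with
    correlated quantitative traits of fixed per-trait QTL heritability, and
    provides native implementations of the canonical-correlation (MANOVA)
    test, a conjugate Bayesian multivariate-regression Bayes factor, the
    reverse proportional-odds regression likelihood-ratio test, a
    partition-averaged Bayes factor over direct/indirect/unaffected trait
    groups, the principal-component-of-heritability association test, the
    extended-Simes (TATES) combination, and univariate-based procedures
    (per-trait regression, minimum p, first principal component,
    sample-size-weighted meta-analysis, Fisher's method). A permutation
    engine derives empirical significance thresholds that fix the
    false-positive rate and computes power tables across scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
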