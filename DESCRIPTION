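Package: eigenmet
Title: Metabolite Correlation-Network Condensation and Module-Eigenvalue GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condenses non-targeted LC-MS feature matrices into weighted
    unsigned correlation-network modules and per-sample module eigenvalues,
    prunes networks at connectivity standard-deviation thresholds, and uses
    the eigenvalues as traits in a kinship-aware mixed linear model GWAS with
    two-level FDR control. External phenotypes can be regressed on module
    eigenvalues by stepwise selection with a partial sum-of-squares ANOVA
    table. Spectral utilities reconstruct indiscriminant MS/MS spectra from
    dual collision-energy feature tables, infer charge states from isotope
    spacing, compute neutral and conjugate masses, and read and write NIST
    msp spectral libraries. A synthetic cohort generator (structured inbred
    genotypes, factor-model metabolomes, polygenic phenotypes, spectra
    fixtures) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
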