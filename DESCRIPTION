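Package: cismr
Title: Cis Mendelian Randomization with Correlated Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Drug-target cis Mendelian randomization from GWAS summary
    statistics. Selects genetic instruments in a gene-centred window
    (F-statistic and minor-allele-frequency filters, p-value-ranked LD
    clumping against a reference panel), harmonizes exposure and outcome
    effect alleles, and estimates causal effects with generalized
    least-squares implementations of the inverse-variance-weighted and
    MR-Egger estimators that model residual linkage disequilibrium.
    Includes leverage- and heterogeneity-based outlier pruning, Cochran-Q
    difference model selection between IVW and Egger, odds-ratio reporting
    with multiplicity control and stratified-estimate interaction tests,
    and a deterministic simulator of two-sample GWAS summary statistics
    with block LD, known causal effects and directional pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
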