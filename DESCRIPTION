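Package: placentaNAAG
Title: Bootstrap-Consistent Differential Expression for Neonatal
    Adiposity-Associated Placental Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies placental genes associated with neonatal adiposity
    within maternal BMI strata using a bootstrap-consistency rule layered on
    a negative-binomial Wald differential-expression engine (median-of-ratios
    depth normalization, method-of-moments dispersion, sex-adjusted design).
    Derives common adiposity-associated genes with concordance
    classification across lean and obese strata, characterizes them by
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    control, coexpression-confirmed interaction networks with hub calling
    and a permutation interaction-enrichment test, cell-type reference
    profiling, and qPCR-style validation statistics. Includes neonatal
    body-composition estimation from anthropometrics, adiposity tertile and
    study-group assignment, cohort summary tables, and a synthetic-data
    generator producing negative-binomial count matrices with planted
    effects plus matching metadata, gene sets, reference matrices and Ct
    tables so every pipeline stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
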