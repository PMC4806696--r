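Package: gsdenovo
Title: Genomic Selection with De Novo GWAS-Derived Fixed-Effect Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-validated genomic selection for inbred breeding populations.
    Implements RR-BLUP/GBLUP prediction in which up to four markers, discovered
    by a mixed-model GWAS run on the training fold, are fitted as fixed effects
    and removed from the genomic relationship matrix. Includes genotype
    import/filtering (VCF, HapMap, dosage tables), VanRaden kinship, a REML
    linear mixed model solver, Wald-test GWAS with Benjamini-Hochberg FDR and
    500 kb peak binning, combinatorial fixed-effect selection, k-medoids
    cluster-aware cross-validation over multi-environment trial data, a
    multiple-linear-regression control, and a breeding-population simulator
    for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    data.table,
    jsonlite,
    yaml,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
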