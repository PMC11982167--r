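Package: pleiometa
Title: Multi-Trait Multi-Environment MetaGWAS for Grain Nutritional Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting stable pleiotropic QTL from
    multi-environment field trials of inbred lines: genotype quality control
    with LD-kNN imputation, per-trial best linear unbiased estimates (BLUEs)
    of line values, a Yang-type genomic relatedness matrix, GREML SNP-based
    heritability and bivariate genetic correlations with element grouping,
    mixed-linear-model association scans, a signed-t multi-trait meta-analysis
    chi-square statistic with Bonferroni significance and LD-based QTL
    clustering, and linkage-disequilibrium decay analysis (loess smoothing,
    background LD, block-size estimation). Includes a synthetic-data generator
    that reproduces the statistical structure the analysis assumes (founder-
    haplotype LD blocks, two negatively correlated trait groups, antagonistic
    pleiotropic loci, randomized-complete-block field layouts), so every stage
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
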