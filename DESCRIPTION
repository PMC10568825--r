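Package: bovmeta
Title: Multi-Population GWAS Meta-Analysis and QTL Calling for Beef Production Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes per-population genome-wide association summary
    statistics for beef production traits, combines them with
    inverse-variance fixed-effects and sample-size-weighted z-score
    meta-analysis, calls quantitative trait loci (QTL) with a
    peak-relative confidence-interval rule, and runs post-GWAS
    annotation, interval-database enrichment, and eQTL/sQTL
    colocalization summaries. Includes a multi-population synthetic-data
    generator (Balding-Nichols allele-frequency divergence, blockwise
    linkage disequilibrium, imputation noise, heterogeneous phenotype
    accuracies) with known ground truth, so the whole pipeline is
    testable without access to animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
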