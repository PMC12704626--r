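Package: stratwas
Title: APOE4-Stratified Cell-Type Transcriptome-Wide Association and Gene
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a stratified discovery-and-prioritization pipeline for
    cell-type-specific transcriptome-wide association studies (cTWAS) of a
    binary disease phenotype, stratified by APOE*4 carrier status.  Provides
    per-stratum logistic genome-wide association scans, fixed-effects and
    sample-size-weighted meta-analysis, cis-heritability screening and
    expression-weight fitting, summary-statistic TWAS, stratum-heterogeneity
    and locus-exclusion filters, approximate-Bayes-factor colocalization,
    summary-data Mendelian randomization with the HEIDI linkage test,
    TMM-normalized pseudobulk differential expression, open-chromatin peak
    overlap, evidence integration across six prioritization layers, and
    drug-target gene-set enrichment.  A synthetic-data generator emulates
    LD-blocked genotypes, stratum-specific liability effects, cell-type
    cis-eQTL architecture and negative-binomial pseudobulk counts so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
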