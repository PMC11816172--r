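Package: wgwas
Title: Weighted GWAS of Repeated Semen Traits via De-Regressed Breeding Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end quantitative-genetics pipeline for repeatedly
    measured boar semen traits: pedigree numerator relationship matrices,
    AI-REML variance components for a repeatability animal model, BLUP
    breeding values with reliabilities, VanRaden deregression to DEBVs,
    reliability-weighted single-SNP mixed-model association with a VanRaden
    genomic relationship matrix, genomic-control diagnostics and
    false-discovery-rate q-values, candidate-gene windowing around
    significant SNPs, cis-eQTL scanning, EM-based linkage-disequilibrium
    estimation, and GWAS/eQTL co-localization. Includes a seeded simulator
    for pedigrees, genotypes with local LD, repeated phenotype records and
    cis-regulated expression so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
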