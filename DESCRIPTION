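Package: canidAIMs
Title: Ancestry-Informative SNP Panels for Wolf, Dog and Jackal Hybridization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate reduced panels of ancestry-informative
    SNP markers (AIMs) that separate natural admixture among divergent wolf
    populations from anthropogenic hybridization with domestic dogs and golden
    jackals. Implements quality filtering of genotype matrices (call-rate,
    linkage-disequilibrium pruning, reference-purity screening), per-locus and
    multi-locus Weir-Cockerham FST, an FST-ranked marker-selection ladder,
    HybridLab-style simulation of F1 and first-backcross genotypes, supervised
    and unsupervised maximum-likelihood admixture estimation with cluster-number
    selection and run alignment, K-means/BIC and DAPC assignment, diversity and
    identity statistics (heterozygosity, allelic richness, PIC, PID, AMOVA,
    gene-flow estimates), and replicate-based genotyping-error QC (consensus
    genotypes, amplification success, allelic dropout and false-allele rates).
    A calibrated multi-population genotype simulator generates test panels whose
    pairwise differentiation matches a target FST matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
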