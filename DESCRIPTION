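Package: pleioscan
Title: Integrating GWAS Summary Statistics with Brain Molecular QTLs to
    Nominate Causal Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for calling genes whose cis- or
    trans-regulated molecular abundance (protein or mRNA) is consistent
    with a causal role in complex brain traits. Combines LD score
    regression genetic correlations, FUSION-style heritability screening
    and predictive weight training, proteome/transcriptome-wide
    association z-scores, summary-data Mendelian randomization with the
    HEIDI linkage filter for cis and trans instruments, Bayesian
    colocalization posteriors, sharing tabulation across trait groups,
    and a constrained bootstrap test for excess protein-protein
    interactions between causal-gene sets. Ships a synthetic-data
    generator with planted truth (block-LD genotypes, correlated
    polygenic traits, cis-heritable molecular traits, mediated signals
    and linkage decoys, trans links, PPI networks with planted edge
    excess) so every stage has parameter-recovery tests without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
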