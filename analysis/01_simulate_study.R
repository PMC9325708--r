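#!/usr/bin/env Rscript
# Generate the synthetic study — block-LD genomes for an LD reference
# panel and a molecular cohort, five correlated GWAS traits with planted
# mediated genes, linkage decoys and trans links, a PPI network with a
# planted inter-set edge excess, and annotation sets — then write every
# input file the pipeline consumes.

source("analysis/00_common.R")

st <- get_study()
man <- write_study(st, "results/study")

lay <- st$genome$layout
message(sprintf("genome: %d SNPs in %d blocks on %d chromosomes; %d genes",
                nrow(lay$snps), nrow(lay$blocks),
                length(unique(lay$snps$CHR)), nrow(lay$genes)))
message(sprintf("cohort: %d samples x %d genes; panel: %d samples",
                nrow(st$abundance), ncol(st$abundance),
                nrow(st$genome$panel)))
message(sprintf("planted: %d pleiotropic links, %d linkage decoys, %d trans links",
                nrow(st$truth$pleiotropic_links),
                nrow(st$truth$linkage_decoys),
                nrow(st$truth$trans_links)))
message(sprintf("PPI: %d edges over %d symbols (planted inter-set fold %.1f)",
                nrow(st$ppi), length(st$ppi_universe), st$truth$ppi_fold))
message("study files written to results/study/ (see manifest.tsv)")
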