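#!/usr/bin/env Rscript
# Cis causal-gene stage, per trait: PWAS-style association z-scores from
# the trained weights, SMR + HEIDI on the cis pQTLs of FDR-significant
# genes, colocalization posteriors, and the A-C / D-E decision rules.

source("analysis/00_common.R")

st <- get_study()
mol <- get_molecular(st)

cis <- lapply(names(st$sumstats), function(tr) {
  message("cis stage for ", tr)
  pipeline_cis_trait(mol, st, tr)
})
names(cis) <- names(st$sumstats)

for (tr in names(cis)) {
  write_tsv(cis[[tr]]$xwas, sprintf("results/xwas_%s.tsv", tr))
  if (!is.null(cis[[tr]]$evidence))
    write_tsv(cis[[tr]]$evidence, sprintf("results/smr_coloc_%s.tsv", tr))
}
calls <- do.call(rbind, lapply(cis, `[[`, "calls"))
write_tsv(calls, "results/cis_calls.tsv")
saveRDS(cis, sprintf("scratch/cis_%d.rds", SEED))

pl <- st$truth$pleiotropic_links
hit <- paste(pl$gene, pl$trait) %in% paste(calls$GENE, calls$TRAIT)
message(sprintf("cis calls: %d gene-trait pairs; sensitivity on planted links %.0f%% (%d/%d)",
                nrow(calls), 100 * mean(hit), sum(hit), nrow(pl)))
dec <- resolve_decoys(st$genome$layout, st$truth, st$config$rho)
dhit <- paste(dec$gene, dec$trait) %in% paste(calls$GENE, calls$TRAIT)
message(sprintf("linkage decoys called causal: %d of %d (HEIDI filters the rest)",
                sum(dhit), nrow(dec)))
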