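#!/usr/bin/env Rscript
# Trans causal-gene stage, per trait: clump genome-wide-significant GWAS
# SNPs (r2 < 0.5 within 250 kb), test each against every gene, flag
# trans pQTLs (> 500 kb or another chromosome, p < 5e-8), then run trans
# SMR + HEIDI (pairs >= 5 Mb apart, instruments from the 500 kb window
# around the trans SNP, Bonferroni multiplicity) and apply criteria
# i-iii.

source("analysis/00_common.R")

st <- get_study()
mol <- get_molecular(st)

trans <- lapply(names(st$sumstats), function(tr) {
  message("trans stage for ", tr)
  pipeline_trans_trait(mol, st, tr)
})
names(trans) <- names(st$sumstats)

tp <- do.call(rbind, lapply(names(trans), function(tr) {
  x <- trans[[tr]]$trans_pqtl
  if (is.null(x)) return(NULL)
  cbind(TRAIT = tr, x[x$SIG, , drop = FALSE])
}))
if (!is.null(tp)) write_tsv(tp, "results/trans_pqtl.tsv")
calls <- do.call(rbind, lapply(trans, `[[`, "calls"))
if (!is.null(calls)) write_tsv(calls, "results/trans_calls.tsv")
saveRDS(trans, sprintf("scratch/trans_%d.rds", SEED))

planted <- merge(st$truth$trans_links, st$truth$pleiotropic_links,
                 by = "gene")
hit <- paste(planted$gene, planted$trait) %in%
  paste(calls$GENE, calls$TRAIT)
message(sprintf("trans calls: %d; planted trans mediation recovered %.0f%% (%d/%d)",
                if (is.null(calls)) 0 else nrow(calls),
                100 * mean(hit), sum(hit), nrow(planted)))
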