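#!/usr/bin/env Rscript
# Molecular-cohort stage: genotype PCs, Haseman-Elston cis heritability
# screen (p < 0.01, HLA excluded), predictive weight training
# (top-SNP / ridge / lasso / elastic net by cross-validated R2), the cis
# pQTL scan, and pi1 replication of lead pQTLs in an independent cohort.

source("analysis/00_common.R")

st <- get_study()
mol <- get_molecular(st)

write_tsv(mol$heritability, "results/heritability.tsv")
message(sprintf("heritable genes: %d of %d (median cis h2 %.2f)",
                sum(mol$heritability$HERITABLE), nrow(mol$heritability),
                median(mol$heritability$H2)))

wtab <- do.call(rbind, lapply(mol$weights, function(w)
  data.frame(GENE = w$gene, MODEL = w$model, CVR2 = w$cvr2,
             NSNP = nrow(w$weights))))
write_tsv(wtab, "results/weights_manifest.tsv")
dir.create("results/weights", showWarnings = FALSE)
for (w in mol$weights)
  data.table::fwrite(w$weights, sprintf("results/weights/%s.tsv", w$gene),
                     sep = "\t")
message(sprintf("weights trained for %d genes (winning models: %s)",
                length(mol$weights),
                paste(names(table(wtab$MODEL)), table(wtab$MODEL),
                      sep = "=", collapse = ", ")))

leads <- mol$cis_pqtl[mol$cis_pqtl$LEAD, ]
write_tsv(mol$cis_pqtl, "results/cis_pqtl.tsv")
message(sprintf("lead cis pQTLs: median |z| = %.1f",
                median(abs(leads$BETA / leads$SE))))

# pi1: lead pQTLs re-tested in an independently drawn replication cohort
cfg2 <- st$config
cfg2$seed <- st$config$seed + 99991L
st2 <- simulate_study(sim_config(seed = cfg2$seed), truth = st$truth,
                      with_ppi = FALSE, with_annotations = FALSE)
rep_scan <- cis_pqtl_scan(st2$genome$cohort, st2$abundance,
                          cbind(st2$covariates,
                                as.data.frame(genotype_pcs(st2$genome$cohort))),
                          st$genome$layout$genes, st$genome$layout$snps)
key <- paste(rep_scan$GENE, rep_scan$SNP)
rep_p <- rep_scan$P[match(paste(leads$GENE, leads$SNP), key)]
pi1 <- estimate_pi1(rep_p[!is.na(rep_p)])
message(sprintf("pi1 replication of %d lead pQTLs: %.2f", pi1$m, pi1$pi1))
write_tsv(data.frame(PI1 = pi1$pi1, PI0 = pi1$pi0, LAMBDA = pi1$lambda,
                     N_LEAD = pi1$m), "results/pi1.tsv")
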