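# End-to-end orchestration of the causal-gene pipeline on a (synthetic or
# real-format) study: LDSC genetic correlations, heritability screen,
# weight training, XWAS, SMR/HEIDI, COLOC, trans analysis, causal calls
# and sharing tabulation.

#' Genetic-correlation stage: LD scores + pairwise rg with FDR
#'
#' Applies the large-effect (chi-square > 80) filter per trait, estimates
#' rg for every trait pair by LD score regression and BH-adjusts across
#' pairs.
#'
#' @param study Study list (uses `genome`, `sumstats`).
#' @param window_kb LD-score window.
#' @param n_blocks Jackknife blocks.
#' @return List `ldscores`, `rg` (data.frame `TRAIT1 TRAIT2 RG SE P Q
#'   tier ...`).
#' @export
pipeline_rg <- function(study, window_kb = 1000, n_blocks = 200) {
  lay <- study$genome$layout
  ldsc <- compute_ld_scores(study$genome$panel, lay$snps, window_kb)
  ref <- lay$snps[, c("SNP", "A1", "A2")]
  ss <- lapply(study$sumstats, function(s)
    filter_large_effects(harmonize_sumstats(s, ref)))
  traits <- names(ss)
  rows <- list()
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    if (j <= i) next
    est <- ldsc_rg(ss[[i]], ss[[j]], ldsc, n_blocks = n_blocks)
    rows[[length(rows) + 1]] <- data.frame(
      TRAIT1 = traits[i], TRAIT2 = traits[j], RG = est$rg, SE = est$se,
      P = est$p, H2_1 = est$h2_1, H2_2 = est$h2_2,
      INT_1 = est$intercept_1, INT_2 = est$intercept_2,
      N_SNP = est$n_snp, FLAGGED = est$flagged, stringsAsFactors = FALSE)
  }
  rg <- do.call(rbind, rows)
  names(rg)[names(rg) == "P"] <- "p"
  rg <- rg_matrix_fdr(rg)
  names(rg)[names(rg) == "p"] <- "P"
  list(ldscores = ldsc, rg = rg)
}

#' Molecular stage: PCs, heritability screen, weights, cis pQTLs
#'
#' @param study Study list.
#' @param n_pcs Genotype principal components to adjust for (default 10).
#' @param h2_p Heritability screen threshold.
#' @param window Cis window (bp).
#' @return List `covariates` (augmented), `heritability`, `weights`
#'   (named list over screened genes), `cis_pqtl`, `dropped` (genes with
#'   no usable weights and their reasons).
#' @export
pipeline_molecular <- function(study, n_pcs = 10, h2_p = 0.01,
                               window = 5e5) {
  lay <- study$genome$layout
  pcs <- genotype_pcs(study$genome$cohort, n_pcs)
  covar <- cbind(study$covariates, as.data.frame(pcs))
  herit <- heritability_screen(study$genome$cohort, study$abundance, covar,
                               lay$genes, lay$snps, window = window,
                               p_cut = h2_p)
  keep <- herit$GENE[herit$HERITABLE]
  weights <- list(); dropped <- character()
  for (g in keep) {
    cis <- cis_window_snps(g, lay$genes, lay$snps, window)
    ws <- fit_weights(study$genome$cohort[, cis, drop = FALSE],
                      study$abundance[, g], covar, lay$snps, gene = g,
                      seed = sub_seed(study$config$seed, paste0("folds-", g)))
    if (is_dropped_gene(ws)) dropped[g] <- attr(ws, "reason")
    else weights[[g]] <- ws
  }
  cis_pqtl <- cis_pqtl_scan(study$genome$cohort, study$abundance, covar,
                            lay$genes, lay$snps, window = window)
  list(covariates = covar, heritability = herit, weights = weights,
       cis_pqtl = cis_pqtl, dropped = dropped)
}

#' Cis association stage for one trait: XWAS + SMR/HEIDI + COLOC + calls
#'
#' Runs the XWAS over all weighted genes; for FDR-significant genes runs
#' SMR with the HEIDI filter on the gene's cis pQTLs and colocalization
#' over the cis window, then applies the cis decision rules.
#'
#' @param mol Output of [pipeline_molecular()].
#' @param study Study list.
#' @param trait Trait name.
#' @param thresholds [pipeline_thresholds()].
#' @return List `xwas`, `evidence` (per significant gene: SMR/HEIDI/COLOC
#'   statistics), `calls` (data.frame, possibly empty).
#' @export
pipeline_cis_trait <- function(mol, study, trait,
                               thresholds = pipeline_thresholds()) {
  lay <- study$genome$layout
  ref <- lay$snps[, c("SNP", "A1", "A2")]
  ss <- harmonize_sumstats(study$sumstats[[trait]], ref)
  xw <- run_xwas(mol$weights, ss, study$genome$panel, trait = trait,
                 fdr_cut = thresholds$xwas_fdr)
  ev <- list(); calls <- list()
  for (g in xw$GENE[xw$SIG]) {
    pq <- mol$cis_pqtl[mol$cis_pqtl$GENE == g, ]
    sh <- tryCatch(smr_with_heidi(pq, ss, study$genome$panel),
                   error = function(e) NULL)
    cl <- tryCatch(coloc_region(ss, pq), error = function(e) NULL)
    if (is.null(sh) && is.null(cl)) next
    rec <- data.frame(
      GENE = g, TRAIT = trait, FDR_P = xw$FDR[xw$GENE == g],
      SMR_P = if (!is.null(sh)) sh$smr$p else NA_real_,
      HEIDI_P = if (!is.null(sh)) sh$heidi$p else NA_real_,
      HEIDI_SKIPPED = if (!is.null(sh)) sh$heidi$skipped else TRUE,
      B_XY = if (!is.null(sh)) sh$smr$b_xy else NA_real_,
      PP4 = if (!is.null(cl)) unname(cl$pp["PP4"]) else NA_real_,
      stringsAsFactors = FALSE)
    ev[[g]] <- rec
    route <- call_cis_causal(rec$FDR_P, rec$SMR_P, rec$HEIDI_P, rec$PP4,
                             thresholds)
    if (!is.null(route))
      calls[[g]] <- cbind(rec[, c("GENE", "TRAIT")], MODE = "cis",
                          ROUTE = route,
                          rec[, c("FDR_P", "SMR_P", "HEIDI_P", "PP4")])
  }
  list(xwas = xw, evidence = do.call(rbind, ev),
       calls = do.call(rbind, calls))
}

#' Trans stage for one trait: clumping, trans pQTLs, trans SMR, calls
#'
#' @param mol Output of [pipeline_molecular()].
#' @param study Study list.
#' @param trait Trait name.
#' @param thresholds [pipeline_thresholds()].
#' @param wind Half-width of the HEIDI window around the trans SNP (bp).
#' @return List `clumped`, `trans_pqtl`, `evidence`, `calls`.
#' @export
pipeline_trans_trait <- function(mol, study, trait,
                                 thresholds = pipeline_thresholds(),
                                 wind = 5e5) {
  lay <- study$genome$layout
  ref <- lay$snps[, c("SNP", "A1", "A2")]
  ss <- harmonize_sumstats(study$sumstats[[trait]], ref)
  clumped <- clump_gwas_hits(ss, study$genome$panel,
                             p_cut = thresholds$gwas_p)
  if (!length(clumped))
    return(list(clumped = clumped, trans_pqtl = NULL, evidence = NULL,
                calls = NULL))
  tp <- trans_pqtl_scan(clumped, study$genome$cohort, study$abundance,
                        mol$covariates, lay$genes, lay$snps,
                        p_cut = thresholds$gwas_p)
  sig <- tp[tp$SIG, , drop = FALSE]
  if (!nrow(sig))
    return(list(clumped = clumped, trans_pqtl = tp, evidence = NULL,
                calls = NULL))
  ev <- list()
  for (r in seq_len(nrow(sig))) {
    rec <- sig[r, ]
    # local pQTL scan of the gene against the window around the trans SNP
    win_snps <- lay$snps$SNP[lay$snps$CHR == rec$CHR &
                               abs(lay$snps$BP - rec$BP) <= wind]
    loc <- .marginal_ols(
      .resid_covar(study$genome$cohort[, win_snps, drop = FALSE],
                   mol$covariates),
      drop(.resid_covar(study$abundance[, rec$GENE, drop = FALSE],
                        mol$covariates)),
      nrow(study$abundance) - ncol(as.matrix(mol$covariates)) - 2)
    loc$SNP <- win_snps
    sh <- tryCatch(
      trans_smr(rec, loc[, c("SNP", "BETA", "SE", "P")], ss,
                study$genome$panel),
      error = function(e) NULL)
    if (is.null(sh)) next
    ev[[length(ev) + 1]] <- data.frame(
      GENE = rec$GENE, TRAIT = trait, SNP = rec$SNP, PQTL_P = rec$P,
      SMR_P = sh$smr$p, HEIDI_P = sh$heidi$p,
      HEIDI_SKIPPED = sh$heidi$skipped, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  calls <- NULL
  if (!is.null(ev) && nrow(ev)) {
    pass <- trans_smr_pass(ev$SMR_P, n_sig = nrow(sig),
                           rule = thresholds$trans_rule)
    keep <- vapply(seq_len(nrow(ev)), function(i)
      !is.null(call_trans_causal(ev$PQTL_P[i], pass[i], ev$HEIDI_P[i],
                                 thresholds)), logical(1))
    if (any(keep)) {
      calls <- data.frame(GENE = ev$GENE[keep], TRAIT = trait,
                          MODE = "trans", ROUTE = "SMR_HEIDI",
                          FDR_P = NA_real_, SMR_P = ev$SMR_P[keep],
                          HEIDI_P = ev$HEIDI_P[keep], PP4 = NA_real_,
                          stringsAsFactors = FALSE)
      # several clumped SNPs in LD can tag the same mediation; keep the
      # strongest record per gene x trait
      calls <- calls[order(calls$SMR_P), ]
      calls <- calls[!duplicated(calls[, c("GENE", "TRAIT")]), ]
    }
  }
  list(clumped = clumped, trans_pqtl = tp, evidence = ev, calls = calls)
}

#' Run the full pipeline on a study
#'
#' @param study Study list from [simulate_study()] (or assembled from
#'   [read_study()] output).
#' @param thresholds [pipeline_thresholds()].
#' @param do_rg Run the LDSC stage (the slowest; default TRUE).
#' @param do_trans Run the trans stage per trait.
#' @return List `rg` (or NULL), `molecular`, `cis` (per trait),
#'   `trans` (per trait), `calls` (combined data.frame), `sharing`.
#' @export
run_pipeline <- function(study, thresholds = pipeline_thresholds(),
                         do_rg = TRUE, do_trans = TRUE) {
  rg <- if (do_rg) pipeline_rg(study) else NULL
  mol <- pipeline_molecular(study, h2_p = thresholds$h2_p)
  traits <- names(study$sumstats)
  cis <- lapply(traits, function(tr)
    pipeline_cis_trait(mol, study, tr, thresholds))
  names(cis) <- traits
  trans <- NULL
  if (do_trans) {
    trans <- lapply(traits, function(tr)
      pipeline_trans_trait(mol, study, tr, thresholds))
    names(trans) <- traits
  }
  calls <- do.call(rbind, c(
    lapply(cis, `[[`, "calls"),
    if (do_trans) lapply(trans, `[[`, "calls")
  ))
  rownames(calls) <- NULL
  sharing <- if (!is.null(calls) && nrow(calls))
    tabulate_sharing(calls, study$groups) else NULL
  list(rg = rg, molecular = mol, cis = cis, trans = trans, calls = calls,
       sharing = sharing)
}
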