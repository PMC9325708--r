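# PWAS/TWAS: combine trained cis weights with GWAS summary statistics and
# reference-panel LD into a gene-level association z-score. The same
# machinery serves proteins and mRNAs; the molecular modality is a label.

#' Gene-level association z-score from weights + summary statistics
#'
#' `z = w'Z / sqrt(w'Rw)` where Z is the harmonized GWAS z-vector over the
#' weight SNPs and R the reference LD submatrix (ridge-regularized by
#' 1e-6 on the diagonal). Weight SNPs missing from the sumstats are
#' dropped without renormalization (the weights are used as-is over the
#' intersection); the dropped count is attached as an attribute.
#'
#' @param weights data.frame `SNP A1 A2 WEIGHT`.
#' @param ss GWAS sumstats (`SNP A1 A2 Z`).
#' @param panel Panel dosage matrix (columns named by SNP, orientation
#'   matching the weight alleles).
#' @return z (scalar) with attributes `n_snp` (used) and `n_dropped`.
#' @export
xwas_z <- function(weights, ss, panel) {
  hs <- harmonize_sumstats(ss[ss$SNP %in% weights$SNP, , drop = FALSE],
                           weights[, c("SNP", "A1", "A2")])
  i <- match(weights$SNP, hs$SNP)
  use <- !is.na(i)
  if (!any(use)) stop_cfg("no weight SNPs present in sumstats")
  w <- weights$WEIGHT[use]
  z <- hs$Z[i[use]]
  xs <- .std_geno(panel[, weights$SNP[use], drop = FALSE])
  R <- crossprod(xs) / (nrow(xs) - 1)
  diag(R) <- diag(R) + 1e-6
  denom <- drop(t(w) %*% R %*% w)
  if (denom < 1e-8) stop_cfg("degenerate weight variance (w'Rw < 1e-8)")
  out <- sum(w * z) / sqrt(denom)
  attr(out, "n_snp") <- sum(use)
  attr(out, "n_dropped") <- sum(!use)
  out
}

#' Run the PWAS/TWAS across all genes for one trait
#'
#' One record per gene with a usable weight set; two-sided normal p and
#' Benjamini-Hochberg FDR within the trait; the significant set is
#' FDR p < `fdr_cut`.
#'
#' @param weight_sets List of [fit_weights()] results (NULL entries are
#'   skipped).
#' @param ss GWAS sumstats for the trait.
#' @param panel Panel dosage matrix.
#' @param trait Trait label carried into the records.
#' @param fdr_cut Significance threshold on FDR p (default 0.05).
#' @return data.frame `GENE TRAIT Z P FDR MODEL NSNP SIG`.
#' @export
run_xwas <- function(weight_sets, ss, panel, trait = "", fdr_cut = 0.05) {
  weight_sets <- Filter(function(w) !is.null(w) && !is_dropped_gene(w),
                        weight_sets)
  if (!length(weight_sets)) stop_cfg("no genes with usable weights")
  rows <- lapply(weight_sets, function(ws) {
    z <- tryCatch(xwas_z(ws$weights, ss, panel), error = function(e) NULL)
    if (is.null(z)) return(NULL)
    data.frame(GENE = ws$gene, TRAIT = trait, Z = as.numeric(z),
               P = 2 * pnorm(-abs(as.numeric(z))), MODEL = ws$model,
               NSNP = attr(z, "n_snp"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out$FDR <- p.adjust(out$P, method = "BH")
  out$SIG <- out$FDR < fdr_cut
  out[, c("GENE", "TRAIT", "Z", "P", "FDR", "MODEL", "NSNP", "SIG")]
}
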