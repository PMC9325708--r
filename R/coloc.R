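# Bayesian colocalization of GWAS and pQTL signals: Wakefield approximate
# Bayes factors and the single-causal-variant posterior enumeration
# (PP0-PP4), computed in log space.

#' Wakefield log approximate Bayes factor
#'
#' With shrinkage `r = W / (W + se^2)` and `z = beta / se`:
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2`.
#'
#' @param beta,se Marginal effect and standard error (se > 0).
#' @param W Prior variance of the effect (default `0.15^2` on the
#'   standardized scale).
#' @return Vector of log ABFs.
#' @export
wakefield_abf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) stop_cfg("se must be positive")
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Colocalization posteriors from two ABF vectors
#'
#' Standard single-causal-variant enumeration over shared SNPs, in log
#' space: H0 (no association), H1/H2 (one trait only), H3 (two distinct
#' causal variants), H4 (one shared causal variant). An H3 sum that goes
#' negative beyond numerical tolerance is clamped at zero with a warning.
#'
#' @param labf1,labf2 Log-ABF vectors aligned on a shared SNP index.
#' @param p1,p2 Per-SNP prior probabilities of association with each
#'   trait (defaults 1e-4).
#' @param p12 Per-SNP prior of shared association (default 1e-5).
#' @return List `pp` (named numeric PP0..PP4 summing to 1), `n_snp`,
#'   `priors`.
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5) {
  stopifnot(length(labf1) == length(labf2), length(labf1) >= 1)
  if (any(!is.finite(labf1)) || any(!is.finite(labf2)))
    stop_cfg("non-finite log ABF")
  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  l0 <- 0
  l1 <- log(p1) + s1
  l2 <- log(p2) + s2
  l4 <- log(p12) + s12
  l3 <- log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  if (length(labf1) == 1) l3 <- -Inf  # no distinct-variant configuration
  if (!is.finite(l3) && length(labf1) > 1 && s1 + s2 < s12 - 1e-9)
    warning("H3 sum negative beyond tolerance; clamped at 0")
  ls <- c(l0, l1, l2, l3, l4)
  pp <- exp(ls - logsumexp(ls))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  list(pp = pp, n_snp = length(labf1),
       priors = c(p1 = p1, p2 = p2, p12 = p12))
}

#' Colocalize a gene region from GWAS z-scores and pQTL effects
#'
#' Reconstructs standardized GWAS effects from z and N
#' (`se = 1/sqrt(N)`, `beta = z se`), computes both traits' Wakefield
#' ABFs over the shared SNPs and enumerates the posteriors.
#'
#' @param ss GWAS sumstats covering the region.
#' @param pqtl data.frame `SNP BETA SE` for the molecular trait.
#' @param W1,W2 Prior effect variances for trait / molecular trait.
#' @param ... Priors passed to [coloc_posteriors()].
#' @return As [coloc_posteriors()].
#' @export
coloc_region <- function(ss, pqtl, W1 = 0.15^2, W2 = 0.15^2, ...) {
  i <- match(pqtl$SNP, ss$SNP)
  keep <- !is.na(i)
  if (!any(keep)) stop_cfg("no shared SNPs between sumstats and pQTL region")
  pq <- pqtl[keep, , drop = FALSE]
  sg <- ss[i[keep], , drop = FALSE]
  se_g <- 1 / sqrt(sg$N)
  labf1 <- wakefield_abf(sg$Z * se_g, se_g, W1)
  labf2 <- wakefield_abf(pq$BETA, pq$SE, W2)
  coloc_posteriors(labf1, labf2, ...)
}
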