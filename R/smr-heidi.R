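# Summary-data Mendelian randomization (SMR) and the HEIDI linkage
# filter, for cis and trans instruments.

#' SMR mediation test from two z-scores
#'
#' `T_SMR = z_gwas^2 z_pqtl^2 / (z_gwas^2 + z_pqtl^2)`, upper-tail
#' chi-square(1) p. The ratio estimate `b_xy = beta_gwas / beta_pqtl`
#' (equivalently `(z_gwas / z_pqtl) * sqrt(n_p / n_g)` on the standardized
#' scale) quantifies the mediation effect of the molecular trait.
#'
#' @param z_gwas,z_pqtl The instrument SNP's z-scores in the GWAS and the
#'   molecular-trait scan.
#' @return List `T, p`.
#' @export
smr_test <- function(z_gwas, z_pqtl) {
  if (!is.finite(z_gwas) || !is.finite(z_pqtl))
    stop_cfg("non-finite z-score")
  if (z_pqtl == 0) stop_cfg("undefined instrument (z_pqtl = 0)")
  T <- (z_gwas^2 * z_pqtl^2) / (z_gwas^2 + z_pqtl^2)
  list(T = T, p = pchisq(T, df = 1, lower.tail = FALSE))
}

#' Select HEIDI instruments around a top cis SNP
#'
#' Instruments are SNPs with pQTL p below `p_inst`, with r2 to the top
#' SNP inside `[r2_min, r2_max]`, capped at the `max_snps` smallest-p
#' SNPs. Fewer than `min_snps` eligible means HEIDI is skipped (NULL with
#' a `reason` attribute). Thresholds follow the SMR tool's published
#' defaults.
#'
#' @param pqtl data.frame `SNP P` for the region (one gene).
#' @param r2_top Named vector of r2 between each SNP and the top SNP.
#' @param top Top SNP id (excluded from the instrument set).
#' @param p_inst,r2_min,r2_max,max_snps,min_snps Selection thresholds.
#' @return Character vector of instrument SNP ids; zero-length (with a
#'   `reason` attribute) when HEIDI must be skipped.
#' @export
select_heidi_instruments <- function(pqtl, r2_top, top,
                                     p_inst = 1.57e-3, r2_min = 0.05,
                                     r2_max = 0.9, max_snps = 20,
                                     min_snps = 3) {
  cand <- pqtl[pqtl$SNP != top & pqtl$P < p_inst, , drop = FALSE]
  r2 <- r2_top[cand$SNP]
  cand <- cand[!is.na(r2) & r2 >= r2_min & r2 <= r2_max, , drop = FALSE]
  if (nrow(cand) < min_snps) {
    return(structure(character(0),
                     reason = sprintf("only %d eligible instruments (< %d)",
                                      nrow(cand), min_snps)))
  }
  cand$SNP[order(cand$P)][seq_len(min(max_snps, nrow(cand)))]
}

# Imhof evaluation of P(sum lambda_k chi2_1 > q); NA on integration
# failure (caller falls back to Monte Carlo)
.imhof_p <- function(q, lambda) {
  integrand <- function(u) {
    lu <- outer(lambda, u)
    th <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(lu^2)))
    sin(th) / (u * rho)
  }
  val <- tryCatch(
    integrate(integrand, 0, Inf, subdivisions = 500L,
              rel.tol = 1e-8, abs.tol = 1e-10)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  min(max(0.5 + val / pi, 1e-12), 1)
}

# Monte Carlo tail of the same mixture, fixed sub-seed
.mc_weighted_chisq <- function(q, lambda, n_draws = 1e5, seed = 20240701) {
  set.seed(seed)
  draws <- colSums(lambda * matrix(rchisq(n_draws * length(lambda), 1),
                                   length(lambda)))
  (1 + sum(draws >= q)) / (n_draws + 1)
}

#' HEIDI heterogeneity test
#'
#' Tests whether the SMR ratio estimate is homogeneous across instruments
#' in LD with the top SNP — heterogeneity indicates linkage (two distinct
#' causal variants) rather than pleiotropy/causality. Deviations
#' `d_i = b_xy(SNP_i) - b_xy(top)` are standardized with a delta-method
#' covariance built from the LD matrix; the statistic is the sum of
#' squared standardized deviations, whose null is a positively weighted
#' sum of chi-square(1) with weights the eigenvalues of the correlation
#' matrix of the deviations (Imhof evaluation, Monte Carlo fallback with
#' 1e5 draws under a fixed sub-seed).
#'
#' @param beta_gwas,se_gwas,beta_pqtl,se_pqtl Marginal effects and ses for
#'   the instruments plus the top SNP (any common scale).
#' @param R LD correlation matrix over the same SNPs (same order).
#' @param top Index of the top SNP within the vectors.
#' @return List `p, n_instruments, statistic, method` (`imhof` or
#'   `monte-carlo`).
#' @export
heidi_test <- function(beta_gwas, se_gwas, beta_pqtl, se_pqtl, R, top) {
  k <- length(beta_gwas)
  stopifnot(length(se_gwas) == k, length(beta_pqtl) == k,
            length(se_pqtl) == k, nrow(R) == k, ncol(R) == k,
            top >= 1, top <= k)
  if (k < 4) stop_cfg("HEIDI needs >= 3 instruments plus the top SNP")
  idx <- setdiff(seq_len(k), top)
  bG <- beta_gwas; bp <- beta_pqtl
  if (any(bp[c(idx, top)] == 0)) stop_cfg("zero pQTL effect among instruments")

  d <- bG[idx] / bp[idx] - bG[top] / bp[top]
  # delta-method gradients of d_i wrt (bG_i, bG_top, bp_i, bp_top)
  g1 <- 1 / bp[idx]
  g2 <- -1 / bp[top]
  g3 <- -bG[idx] / bp[idx]^2
  g4 <- bG[top] / bp[top]^2
  CG <- R * outer(se_gwas, se_gwas)
  Cp <- R * outer(se_pqtl, se_pqtl)
  V <- outer(g1, g1) * CG[idx, idx, drop = FALSE] +
    outer(g3, g3) * Cp[idx, idx, drop = FALSE]
  tG <- g1 * g2 * CG[idx, top]
  tp <- g3 * g4 * Cp[idx, top]
  V <- V + outer(tG, rep(1, length(idx))) + outer(rep(1, length(idx)), tG) +
    outer(tp, rep(1, length(idx))) + outer(rep(1, length(idx)), tp) +
    g2^2 * CG[top, top] + g4^2 * Cp[top, top]

  sdv <- sqrt(pmax(diag(V), 1e-300))
  zd <- d / sdv
  corr <- V / outer(sdv, sdv)
  corr <- (corr + t(corr)) / 2
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6)
    stop_cfg("deviation covariance not positive semidefinite")
  lambda <- lambda[lambda > 1e-10]
  stat <- sum(zd^2)
  p <- .imhof_p(stat, lambda)
  method <- "imhof"
  if (is.na(p)) {
    p <- .mc_weighted_chisq(stat, lambda)
    method <- "monte-carlo"
  }
  list(p = p, n_instruments = length(idx), statistic = stat,
       method = method)
}

#' SMR + HEIDI for one gene region from summary inputs
#'
#' Convenience wrapper used for both cis and trans instruments: runs the
#' SMR test on the top SNP, selects HEIDI instruments by pQTL p and LD
#' with the top SNP, and runs the HEIDI test. GWAS effects are
#' reconstructed on the standardized scale (`se = 1/sqrt(N)`,
#' `beta = z se`).
#'
#' @param pqtl data.frame `SNP BETA SE P` for the region's SNPs.
#' @param ss GWAS sumstats covering the region (harmonized orientation).
#' @param panel Panel dosage matrix (columns named).
#' @param top Top instrument SNP id (default: smallest pQTL p).
#' @param mode `"cis"` or `"trans"` (label).
#' @param ... Passed to [select_heidi_instruments()].
#' @return List `smr` (`gene`-agnostic: `snp, b_xy, T, p, mode`) and
#'   `heidi` (`p, n_instruments, skipped, reason, method`).
#' @export
smr_with_heidi <- function(pqtl, ss, panel, top = NULL, mode = "cis", ...) {
  i <- match(pqtl$SNP, ss$SNP)
  keep <- !is.na(i)
  pqtl <- pqtl[keep, , drop = FALSE]
  gz <- ss$Z[i[keep]]
  gn <- ss$N[i[keep]]
  if (!nrow(pqtl)) stop_cfg("no region SNPs present in sumstats")
  top <- top %||% pqtl$SNP[order(pqtl$P, pqtl$SNP)][1]
  ti <- match(top, pqtl$SNP)
  zp <- pqtl$BETA / pqtl$SE
  smr <- smr_test(gz[ti], zp[ti])
  b_xy <- (gz[ti] / sqrt(gn[ti])) / pqtl$BETA[ti]
  smr <- list(snp = top, b_xy = b_xy, T = smr$T, p = smr$p, mode = mode)

  xs <- .std_geno(panel[, pqtl$SNP, drop = FALSE])
  Rfull <- crossprod(xs) / (nrow(xs) - 1)
  r2_top <- Rfull[, ti]^2
  names(r2_top) <- pqtl$SNP
  inst <- select_heidi_instruments(pqtl[, c("SNP", "P")], r2_top, top, ...)
  if (!length(inst)) {
    heidi <- list(p = NA_real_, n_instruments = 0L, skipped = TRUE,
                  reason = attr(inst, "reason"), method = NA_character_)
  } else {
    sel <- match(c(inst, top), pqtl$SNP)
    h <- heidi_test(
      beta_gwas = gz[sel] / sqrt(gn[sel]), se_gwas = 1 / sqrt(gn[sel]),
      beta_pqtl = pqtl$BETA[sel], se_pqtl = pqtl$SE[sel],
      R = Rfull[sel, sel], top = length(sel)
    )
    heidi <- list(p = h$p, n_instruments = h$n_instruments,
                  skipped = FALSE, reason = NA_character_,
                  method = h$method)
  }
  list(smr = smr, heidi = heidi)
}

#' Trans SMR + HEIDI for a trans-pQTL record
#'
#' Restricted to SNP-gene pairs at least `min_dist` apart (5 Mb, or on
#' different chromosomes); HEIDI instruments are drawn from the window of
#' `wind` bp centered on the trans-pQTL SNP, whose local pQTL effects on
#' the gene must be supplied.
#'
#' @param trans_record One row of [trans_pqtl_scan()] output (`GENE SNP
#'   DIST ...`).
#' @param local_pqtl data.frame `SNP BETA SE P`: pQTL scan of the gene's
#'   abundance against SNPs within the window around the trans SNP.
#' @param ss GWAS sumstats.
#' @param panel Panel dosage matrix.
#' @param min_dist Minimum SNP-gene distance (default 5 Mb).
#' @param ... Passed to [select_heidi_instruments()].
#' @return As [smr_with_heidi()] with `mode = "trans"`.
#' @export
trans_smr <- function(trans_record, local_pqtl, ss, panel,
                      min_dist = 5e6, ...) {
  if (is.finite(trans_record$DIST) && trans_record$DIST < min_dist)
    stop_cfg("SNP-gene pair only %.0f bp apart (< %.0f): ineligible for trans SMR",
             trans_record$DIST, min_dist)
  smr_with_heidi(local_pqtl, ss, panel, top = trans_record$SNP,
                 mode = "trans", ...)
}

#' Multiplicity threshold for trans SMR results
#'
#' Bonferroni: `0.05 / n_signif_trans_pqtl` (the default rule); FDR mode
#' instead BH-adjusts the supplied SMR p-values and applies 0.05.
#'
#' @param smr_p Vector of trans-SMR p-values.
#' @param n_sig Number of significant trans-pQTLs (Bonferroni denominator).
#' @param rule `"bonferroni"` or `"fdr"`.
#' @param alpha Family-wise/FDR level (default 0.05).
#' @return Logical vector: which SMR results pass.
#' @export
trans_smr_pass <- function(smr_p, n_sig, rule = c("bonferroni", "fdr"),
                           alpha = 0.05) {
  rule <- match.arg(rule)
  if (rule == "bonferroni") smr_p < alpha / max(n_sig, 1)
  else p.adjust(smr_p, "BH") < alpha
}
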