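# LD score regression: SNP heritability and cross-trait genetic
# correlation from summary statistics, with block-jackknife standard
# errors.

#' Compute LD scores from a reference panel
#'
#' For each SNP j, the LD score is the sum of squared sample correlations
#' with all SNPs within `window_kb` on the same chromosome (including
#' itself). With `adjust = TRUE` each r2 gets the unbiased-sample
#' adjustment `r2 - (1 - r2) / (n - 2)`, and per-SNP totals are floored
#' at 0.
#'
#' @param geno Panel dosage matrix (samples x SNPs, columns named).
#' @param snps data.frame `SNP CHR BP` in the same column order as `geno`.
#' @param window_kb Window half-width in kb (default 1000).
#' @param adjust Apply the unbiased r2 adjustment.
#' @return data.frame `SNP CHR BP L2` with attributes `M` (number of
#'   SNPs) and `window_kb`.
#' @export
compute_ld_scores <- function(geno, snps, window_kb = 1000, adjust = TRUE) {
  if (window_kb <= 0) stop_cfg("window_kb must be positive")
  n <- nrow(geno)
  if (n < 3) stop_cfg("panel must have at least 3 samples")
  stopifnot(ncol(geno) == nrow(snps))
  ord <- order(snps$CHR, snps$BP)
  snps <- snps[ord, ]
  xs <- .std_geno(geno[, ord, drop = FALSE])
  win <- window_kb * 1000
  l2 <- numeric(nrow(snps))
  for (chr in unique(snps$CHR)) {
    idx <- which(snps$CHR == chr)
    bp <- snps$BP[idx]
    # segments: SNPs in different segments are > window apart, so their
    # (adjusted) r2 contributes nothing
    seg <- cumsum(c(1, diff(bp) > win))
    for (s in unique(seg)) {
      ii <- idx[seg == s]
      r2 <- crossprod(xs[, ii, drop = FALSE])^2 / (n - 1)^2
      if (adjust) r2 <- r2 - (1 - r2) / (n - 2)
      mask <- abs(outer(snps$BP[ii], snps$BP[ii], "-")) <= win
      l2[ii] <- rowSums(r2 * mask)
    }
  }
  if (adjust) l2 <- pmax(l2, 0)
  out <- data.frame(SNP = snps$SNP, CHR = snps$CHR, BP = snps$BP, L2 = l2,
                    stringsAsFactors = FALSE)
  attr(out, "M") <- nrow(out)
  attr(out, "window_kb") <- window_kb
  out
}

#' LD scores from an exact correlation matrix
#'
#' Windowed sum of (optionally bias-adjusted) squared correlations given a
#' known LD matrix — the population-oracle counterpart of
#' [compute_ld_scores()].
#'
#' @param R Correlation matrix.
#' @param bp Base-pair positions (same order as `R`).
#' @param window_kb Window half-width in kb.
#' @param n Sample size for the unbiased adjustment (NULL = no
#'   adjustment).
#' @return Numeric vector of LD scores.
#' @export
ld_scores_from_corr <- function(R, bp, window_kb = 1000, n = NULL) {
  stopifnot(nrow(R) == length(bp))
  r2 <- R^2
  if (!is.null(n)) r2 <- r2 - (1 - r2) / (n - 2)
  mask <- abs(outer(bp, bp, "-")) <= window_kb * 1000
  rowSums(r2 * mask)
}

#' Harmonize summary statistics to reference alleles
#'
#' Matches by SNP id; flips the z sign (and FREQ) when A1/A2 are swapped
#' relative to the reference; drops strand-ambiguous (A/T, C/G) and
#' unmatched/mismatched SNPs. Counts of each action are attached as
#' attributes.
#'
#' @param ss Sumstats data.frame (`SNP A1 A2 Z`, optional `FREQ`).
#' @param ref data.frame `SNP A1 A2` giving the reference orientation.
#' @return Harmonized sumstats in reference orientation with attributes
#'   `n_flipped`, `n_ambiguous`, `n_unmatched`, `n_mismatched`.
#' @export
harmonize_sumstats <- function(ss, ref) {
  amb <- (ss$A1 == "A" & ss$A2 == "T") | (ss$A1 == "T" & ss$A2 == "A") |
    (ss$A1 == "C" & ss$A2 == "G") | (ss$A1 == "G" & ss$A2 == "C")
  n_amb <- sum(amb)
  ss <- ss[!amb, , drop = FALSE]
  i <- match(ss$SNP, ref$SNP)
  n_unm <- sum(is.na(i))
  keep <- !is.na(i)
  ss <- ss[keep, , drop = FALSE]
  i <- i[keep]
  same <- ss$A1 == ref$A1[i] & ss$A2 == ref$A2[i]
  swap <- ss$A1 == ref$A2[i] & ss$A2 == ref$A1[i]
  n_mis <- sum(!same & !swap)
  ss$Z[swap] <- -ss$Z[swap]
  if ("FREQ" %in% names(ss)) ss$FREQ[swap] <- 1 - ss$FREQ[swap]
  ss$A1[swap] <- ref$A1[i][swap]
  ss$A2[swap] <- ref$A2[i][swap]
  out <- ss[same | swap, , drop = FALSE]
  if (nrow(out) == 0) stop_cfg("no SNPs overlap the reference after harmonization")
  attr(out, "n_flipped") <- sum(swap)
  attr(out, "n_ambiguous") <- n_amb
  attr(out, "n_unmatched") <- n_unm
  attr(out, "n_mismatched") <- n_mis
  out
}

#' Remove SNPs with extremely large effects before LD score regression
#'
#' Drops SNPs with chi-square (z^2) above `max_chisq` (default 80), which
#' would otherwise unduly influence the regression.
#'
#' @param ss Sumstats data.frame.
#' @param max_chisq Removal threshold on z^2.
#' @return Filtered sumstats with attribute `n_removed`.
#' @export
filter_large_effects <- function(ss, max_chisq = 80) {
  drop <- ss$Z^2 > max_chisq
  out <- ss[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

# closed-form weighted least squares of y on x with intercept;
# returns c(intercept, slope)
.wls_fit <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x * x); swxy <- sum(w * x * y)
  den <- sw * swxx - swx^2
  if (abs(den) < 1e-12 * sw * swxx || !is.finite(den) || den == 0)
    stop_cfg("degenerate regression design (constant LD scores?)")
  slope <- (sw * swxy - swx * swy) / den
  int <- (swy - slope * swx) / sw
  c(int, slope)
}

# leave-one-block-out WLS slopes/intercepts; blocks are n_blocks
# contiguous chunks in the given order
.wls_jack <- function(x, y, w, n_blocks) {
  m <- length(x)
  n_blocks <- min(n_blocks, m)
  blk <- ceiling(seq_along(x) / (m / n_blocks))
  agg <- function(v) vapply(split(v, blk), sum, numeric(1))
  sw <- agg(w); swx <- agg(w * x); swy <- agg(w * y)
  swxx <- agg(w * x * x); swxy <- agg(w * x * y)
  tot <- c(sum(sw), sum(swx), sum(swy), sum(swxx), sum(swxy))
  loo <- cbind(tot[1] - sw, tot[2] - swx, tot[3] - swy, tot[4] - swxx,
               tot[5] - swxy)
  den <- loo[, 1] * loo[, 4] - loo[, 2]^2
  slope <- (loo[, 1] * loo[, 5] - loo[, 2] * loo[, 3]) / den
  int <- (loo[, 3] - slope * loo[, 2]) / loo[, 1]
  list(fit = .wls_fit(x, y, w), loo = cbind(int = int, slope = slope),
       n_blocks = max(blk))
}

.jack_se <- function(loo_vals) {
  b <- length(loo_vals)
  sqrt((b - 1) / b * sum((loo_vals - mean(loo_vals))^2))
}

#' Estimate SNP heritability by LD score regression
#'
#' Weighted least squares of chi-square on `N * L2 / M` with a free
#' intercept; the slope is h2. Heteroskedasticity weights
#' `1 / (1 + N h2 L2 / M)^2` are recomputed once from a first pass.
#' Standard errors come from a contiguous-block jackknife.
#'
#' @param ss Sumstats (harmonized).
#' @param ldscores Output of [compute_ld_scores()].
#' @param M Number of regression SNPs (defaults to the LD-score table's).
#' @param n_blocks Jackknife blocks (default 200).
#' @param min_snps Minimum merged SNPs required (default 200).
#' @return List `h2, h2_se, intercept, intercept_se, n_snp`.
#' @export
ldsc_h2 <- function(ss, ldscores, M = NULL, n_blocks = 200,
                    min_snps = 200) {
  M <- M %||% attr(ldscores, "M")
  i <- match(ldscores$SNP, ss$SNP)
  keep <- !is.na(i)
  if (sum(keep) < min_snps)
    stop_cfg("only %d SNPs merged with LD scores (need >= %d)",
             sum(keep), min_snps)
  l2 <- ldscores$L2[keep]
  sss <- ss[i[keep], ]
  chi2 <- sss$Z^2
  x <- sss$N * l2 / M
  f0 <- .wls_fit(x, chi2, rep(1, length(x)))
  w <- 1 / pmax(1 + sss$N * max(f0[2], 0) * l2 / M, 0.1)^2
  j <- .wls_jack(x, chi2, w, n_blocks)
  list(
    h2 = j$fit[2], h2_se = .jack_se(j$loo[, "slope"]),
    intercept = j$fit[1], intercept_se = .jack_se(j$loo[, "int"]),
    n_snp = length(x)
  )
}

#' Estimate cross-trait genetic correlation by LD score regression
#'
#' Regression of `z1 * z2` on `sqrt(N1 N2) * L2 / M` with a free intercept
#' (which absorbs sample overlap); the slope is the genetic covariance and
#' `rg = gencov / sqrt(h1^2_est * h2^2_est)`. The jackknife recomputes all
#' three regressions per deleted block, so the se reflects the full ratio.
#'
#' @param ss1,ss2 Harmonized sumstats for the two traits (same SNP
#'   orientation).
#' @param ldscores Output of [compute_ld_scores()].
#' @param M,n_blocks,min_snps As in [ldsc_h2()].
#' @return List `rg, se, z, p, gencov, h2_1, h2_2, intercept_1,
#'   intercept_2, gencov_intercept, n_snp, flagged` (TRUE when |rg| > 1.25
#'   or either h2 <= 0, in which case rg is NA).
#' @export
ldsc_rg <- function(ss1, ss2, ldscores, M = NULL, n_blocks = 200,
                    min_snps = 200) {
  M <- M %||% attr(ldscores, "M")
  i1 <- match(ldscores$SNP, ss1$SNP)
  i2 <- match(ldscores$SNP, ss2$SNP)
  keep <- !is.na(i1) & !is.na(i2)
  if (sum(keep) < min_snps)
    stop_cfg("only %d SNPs shared across traits and LD scores", sum(keep))
  l2 <- ldscores$L2[keep]
  s1 <- ss1[i1[keep], ]; s2 <- ss2[i2[keep], ]
  s1$N <- as.numeric(s1$N); s2$N <- as.numeric(s2$N)
  x1 <- s1$N * l2 / M
  x2 <- s2$N * l2 / M
  xc <- sqrt(s1$N * s2$N) * l2 / M

  f1 <- .wls_fit(x1, s1$Z^2, rep(1, length(l2)))
  f2 <- .wls_fit(x2, s2$Z^2, rep(1, length(l2)))
  w1 <- pmax(1 + s1$N * max(f1[2], 0) * l2 / M, 0.1)
  w2 <- pmax(1 + s2$N * max(f2[2], 0) * l2 / M, 0.1)
  j1 <- .wls_jack(x1, s1$Z^2, 1 / w1^2, n_blocks)
  j2 <- .wls_jack(x2, s2$Z^2, 1 / w2^2, n_blocks)
  jc <- .wls_jack(xc, s1$Z * s2$Z, 1 / (w1 * w2), n_blocks)

  h1 <- j1$fit[2]; h2 <- j2$fit[2]; gc <- jc$fit[2]
  flagged <- FALSE
  if (h1 <= 0 || h2 <= 0) {
    return(list(rg = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                gencov = gc, h2_1 = h1, h2_2 = h2,
                intercept_1 = j1$fit[1], intercept_2 = j2$fit[1],
                gencov_intercept = jc$fit[1], n_snp = length(l2),
                flagged = TRUE))
  }
  rg <- gc / sqrt(h1 * h2)
  hp1 <- pmax(j1$loo[, "slope"], 1e-9)
  hp2 <- pmax(j2$loo[, "slope"], 1e-9)
  rg_loo <- jc$loo[, "slope"] / sqrt(hp1 * hp2)
  se <- .jack_se(rg_loo)
  z <- rg / se
  if (abs(rg) > 1.25) flagged <- TRUE
  list(rg = rg, se = se, z = z, p = 2 * pnorm(-abs(z)), gencov = gc,
       h2_1 = h1, h2_2 = h2, intercept_1 = j1$fit[1],
       intercept_2 = j2$fit[1], gencov_intercept = jc$fit[1],
       n_snp = length(l2), flagged = flagged)
}

#' FDR-adjust a table of genetic-correlation estimates
#'
#' Benjamini-Hochberg across all trait pairs, with significance tiers at
#' FDR 0.05 / 0.01 / 0.001.
#'
#' @param estimates data.frame with at least a `p` column.
#' @return The table with added `q` and `tier` (`***`, `**`, `*`, ``).
#' @export
rg_matrix_fdr <- function(estimates) {
  stopifnot(nrow(estimates) >= 1, "p" %in% names(estimates))
  estimates$q <- p.adjust(estimates$p, method = "BH")
  estimates$tier <- as.character(cut(
    estimates$q, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
    labels = c("***", "**", "*", "")
  ))
  estimates
}
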