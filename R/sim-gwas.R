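#' Per-gene target cis heritabilities
#'
#' Recycles the config's `cis_h2` over the genes of a layout.
#'
#' @param layout Genome layout.
#' @param config A [sim_config()] object.
#' @return Named numeric vector, one entry per gene.
#' @export
gene_cis_h2 <- function(layout, config) {
  h2 <- rep(config$cis_h2, length.out = nrow(layout$genes))
  names(h2) <- layout$genes$GENE
  h2
}

#' Resolve linkage-decoy SNPs on the genome layout
#'
#' A linkage decoy is a trait-causal SNP distinct from a gene's
#' abundance-causal SNP but in LD with it. Under the AR(1) block model the
#' latent correlation at lag d is rho^d, so the decoy is placed
#' `round(log(r2) / (2 log rho))` SNPs away from the cis-causal SNP,
#' staying inside the block.
#'
#' @param layout Genome layout.
#' @param truth Planted truth.
#' @param rho Within-block AR(1) parameter used by the generator.
#' @return `linkage_decoys` with an added `snp` column (NULL if no decoys).
#' @export
resolve_decoys <- function(layout, truth, rho) {
  dec <- truth$linkage_decoys
  if (is.null(dec) || nrow(dec) == 0) return(NULL)
  snps <- layout$snps
  dec$snp <- vapply(seq_len(nrow(dec)), function(i) {
    g <- layout$genes[layout$genes$GENE == dec$gene[i], ]
    ci <- match(g$CIS_SNP, snps$SNP)
    lag <- max(1L, as.integer(round(log(dec$r2[i]) / (2 * log(abs(rho))))))
    blk <- which(snps$BLOCK == snps$BLOCK[ci])
    j <- if ((ci + lag) <= max(blk)) ci + lag else ci - lag
    snps$SNP[j]
  }, character(1))
  dec
}

# Joint per-SNP standardized effect matrix (n_snp x n_trait):
# polygenic background with cross-trait correlation rg plus planted
# mediated, decoy and trans-mediated components
.effect_matrix <- function(layout, truth, config) {
  snps <- layout$snps
  m <- nrow(snps)
  k <- length(truth$traits)
  h2 <- rep(config$trait_h2, length.out = k)
  set.seed(sub_seed(config$seed, "gwas-effects"))
  # matrix square root of D Rg D (eigen; chol fails on singular targets)
  dmat <- diag(sqrt(h2 / m), k)
  sig <- dmat %*% truth$rg_matrix %*% dmat
  es <- eigen(sig, symmetric = TRUE)
  sq <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors)
  a <- matrix(rnorm(m * k), m, k) %*% sq
  colnames(a) <- truth$traits

  cish2 <- gene_cis_h2(layout, config)
  pl <- truth$pleiotropic_links
  if (!is.null(pl)) {
    for (i in seq_len(nrow(pl))) {
      g <- layout$genes[layout$genes$GENE == pl$gene[i], ]
      j <- match(g$CIS_SNP, snps$SNP)
      a[j, pl$trait[i]] <- a[j, pl$trait[i]] +
        pl$b_xy[i] * sqrt(cish2[pl$gene[i]])
      tl <- truth$trans_links
      if (!is.null(tl)) {
        tl <- tl[tl$gene == pl$gene[i], , drop = FALSE]
        for (r in seq_len(nrow(tl))) {
          jt <- match(tl$snp[r], snps$SNP)
          a[jt, pl$trait[i]] <- a[jt, pl$trait[i]] + pl$b_xy[i] * tl$effect[r]
        }
      }
    }
  }
  dec <- resolve_decoys(layout, truth, config$rho)
  if (!is.null(dec)) {
    for (i in seq_len(nrow(dec))) {
      j <- match(dec$snp[i], snps$SNP)
      a[j, dec$trait[i]] <- a[j, dec$trait[i]] + dec$gwas_beta[i]
    }
  }
  a
}

#' Simulate GWAS summary statistics for one trait
#'
#' Traits are simulated at summary level: within each LD block the z-score
#' vector is drawn from MVN(sqrt(N) R a, R) where R is the block's
#' latent-scale LD matrix and a the joint per-SNP standardized effects.
#' The polygenic component is drawn once for all traits jointly (sub-seed
#' independent of trait) with cross-trait correlation equal to the target
#' genetic correlation, so any pair of generated traits realizes its
#' planted rg; per-trait noise uses a trait-specific sub-seed, i.e. zero
#' sample overlap.
#'
#' @param genome Output of [simulate_genome()] (only `layout` is used).
#' @param truth Planted truth from [plant_truth()].
#' @param config A [sim_config()] object.
#' @param trait Trait name; must appear in `truth$traits`.
#' @return A sumstats data.frame `SNP CHR BP A1 A2 Z N FREQ`.
#' @export
simulate_gwas <- function(genome, truth, config, trait) {
  layout <- genome$layout
  if (!trait %in% truth$traits)
    stop_cfg("trait '%s' is not defined in the planted truth", trait)
  a <- .effect_matrix(layout, truth, config)[, trait]
  snps <- layout$snps
  n <- config$n_gwas
  set.seed(sub_seed(config$seed, paste0("gwas-noise-", trait)))
  z <- numeric(nrow(snps))
  for (b in unique(snps$BLOCK)) {
    idx <- which(snps$BLOCK == b)
    m <- length(idx)
    # dosage-scale population LD: what the panel genotypes realize, hence
    # what LD-score regression sees
    R <- dosage_ld(snps$MAF[idx], config$rho)
    U <- chol(R + diag(1e-8, m))
    mu <- sqrt(n) * drop(R %*% a[idx])
    z[idx] <- mu + drop(crossprod(U, rnorm(m)))
  }
  data.frame(
    SNP = snps$SNP, CHR = snps$CHR, BP = snps$BP, A1 = snps$A1,
    A2 = snps$A2, Z = z, N = as.numeric(n), FREQ = snps$MAF,
    stringsAsFactors = FALSE
  )
}

#' Simulate paired GWAS and pQTL summary statistics for one LD region
#'
#' Small-region oracle used to calibrate SMR/HEIDI: given standardized
#' causal effects for the trait and for the molecular trait, marginal
#' effects are R b_causal and estimated effects are drawn as
#' MVN(R b, R / n) on the standardized-beta scale (so se = 1/sqrt(n)).
#' Pleiotropy corresponds to `causal_gwas` and `causal_pqtl` loading the
#' same SNP; a linkage decoy loads two different SNPs in LD.
#'
#' @param m Number of SNPs in the region.
#' @param rho AR(1) LD parameter.
#' @param n_gwas,n_pqtl Sample sizes for the two studies.
#' @param causal_gwas,causal_pqtl Numeric effect vectors of length `m`
#'   (standardized per-allele effects; mostly zero).
#' @param seed Integer seed.
#' @return List with `z_gwas`, `z_pqtl`, `beta_gwas`, `se_gwas`,
#'   `beta_pqtl`, `se_pqtl`, and the LD matrix `R`.
#' @export
simulate_region <- function(m, rho, n_gwas, n_pqtl, causal_gwas,
                            causal_pqtl, seed = 1L) {
  stopifnot(length(causal_gwas) == m, length(causal_pqtl) == m)
  set.seed(seed)
  R <- ar1_ld(m, rho)
  U <- chol(R)
  bg <- drop(R %*% causal_gwas)
  bp <- drop(R %*% causal_pqtl)
  bg_hat <- bg + drop(crossprod(U, rnorm(m))) / sqrt(n_gwas)
  bp_hat <- bp + drop(crossprod(U, rnorm(m))) / sqrt(n_pqtl)
  list(
    z_gwas = bg_hat * sqrt(n_gwas), z_pqtl = bp_hat * sqrt(n_pqtl),
    beta_gwas = bg_hat, se_gwas = rep(1 / sqrt(n_gwas), m),
    beta_pqtl = bp_hat, se_pqtl = rep(1 / sqrt(n_pqtl), m),
    R = R
  )
}
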