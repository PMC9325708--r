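#' Simulate a block-LD genome, reference panel and molecular cohort
#'
#' Builds an ordered set of independent LD blocks spread over `n_chrom`
#' chromosomes, then draws two genotype matrices (LD reference panel and
#' molecular cohort) from the same population. Within a block, genotypes
#' come from a Gaussian copula: two latent AR(1) haplotype draws with
#' parameter `rho` are thresholded at the MAF quantile, so adjacent SNPs
#' follow the latent-scale correlation pattern `rho^|i-j|` and blocks are
#' uncorrelated by construction. Genes are placed one per block, centred on
#' the block's middle SNP, which also serves as the gene's abundance-causal
#' cis SNP.
#'
#' @param config A [sim_config()] object.
#' @return A list with `layout` (list of `snps`, `blocks`, `genes`
#'   data.frames), `panel` and `cohort` (0/1/2 dosage matrices of the A1
#'   allele, columns named by SNP id).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "pleioscan_config"))
  set.seed(sub_seed(config$seed, "genome"))
  nb <- config$n_blocks; m <- config$block_size
  chrom <- rep(seq_len(config$n_chrom), length.out = nb)
  chrom <- sort(chrom)

  snps <- vector("list", nb)
  pos0 <- 1e6
  last_chr <- 0L
  for (b in seq_len(nb)) {
    if (chrom[b] != last_chr) { pos0 <- 1e6; last_chr <- chrom[b] }
    bp <- pos0 + (seq_len(m) - 1L) * config$snp_spacing
    pos0 <- bp[m] + config$block_gap
    snps[[b]] <- data.frame(
      BLOCK = b, CHR = as.character(chrom[b]), BP = bp,
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, snps)
  n_snp <- nrow(snps)
  snps$SNP <- sprintf("rs%07d", seq_len(n_snp))
  snps$MAF <- runif(n_snp, config$maf_range[1], config$maf_range[2])
  # non-strand-ambiguous allele pairs only (A/T and C/G pairs are dropped
  # during harmonization, which would silently thin the simulated genome)
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(4L, n_snp, replace = TRUE)
  snps$A1 <- pairs[pick, 1]
  snps$A2 <- pairs[pick, 2]
  snps <- snps[, c("SNP", "CHR", "BP", "A1", "A2", "MAF", "BLOCK")]

  gene_blocks <- seq_len(config$n_genes)
  mid <- vapply(gene_blocks, function(b) {
    idx <- which(snps$BLOCK == b)
    idx[ceiling(length(idx) / 2)]
  }, integer(1))
  genes <- data.frame(
    GENE = sprintf("GENE%04d", seq_len(config$n_genes)),
    CHR = snps$CHR[mid],
    START = pmax(1, snps$BP[mid] - 5000),
    END = snps$BP[mid] + 5000,
    BLOCK = gene_blocks,
    CIS_SNP = snps$SNP[mid],
    stringsAsFactors = FALSE
  )
  blocks <- data.frame(
    BLOCK = seq_len(nb), CHR = as.character(chrom),
    N_SNP = m, RHO = config$rho
  )
  layout <- list(snps = snps, blocks = blocks, genes = genes)

  panel <- .draw_genotypes(layout, config$n_panel, config$rho)
  cohort <- .draw_genotypes(layout, config$n_cohort, config$rho)
  list(layout = layout, panel = panel, cohort = cohort)
}

# One latent AR(1) haplotype matrix (n x m), unit marginals
.latent_ar1 <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), n, m)
  if (rho != 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

# 0/1/2 A1-dosages for all blocks; Gaussian-copula thresholding at the
# MAF quantile so E[dosage] = 2*MAF under HWE
.draw_genotypes <- function(layout, n, rho) {
  snps <- layout$snps
  g <- matrix(0L, n, nrow(snps))
  for (b in unique(snps$BLOCK)) {
    idx <- which(snps$BLOCK == b)
    q <- qnorm(snps$MAF[idx], lower.tail = FALSE)
    qm <- matrix(q, n, length(idx), byrow = TRUE)
    g[, idx] <- (.latent_ar1(n, length(idx), rho) > qm) +
      (.latent_ar1(n, length(idx), rho) > qm)
  }
  colnames(g) <- snps$SNP
  g
}

# column-standardize a dosage matrix; monomorphic columns become 0
.std_geno <- function(g) {
  mu <- colMeans(g)
  sd <- apply(g, 2, sd)
  sd[sd == 0] <- Inf
  sweep(sweep(g, 2, mu), 2, sd, "/")
}

#' Population dosage-scale LD matrix of one block
#'
#' Under the Gaussian-copula model, the correlation between two 0/1/2
#' dosages with latent correlation r and thresholds at the MAF quantiles
#' follows from Mehler's tetrachoric expansion:
#' `cov(I_a, I_b) = phi(a) phi(b) sum_k r^k / k! He_{k-1}(a) He_{k-1}(b)`
#' per haplotype, with He the probabilists' Hermite polynomials. This is
#' the LD the panel genotypes realize, and the scale on which GWAS
#' z-scores are simulated.
#'
#' @param maf Minor-allele frequencies of the block's SNPs.
#' @param rho Latent AR(1) parameter.
#' @param n_terms Series terms (default 50; the series converges
#'   geometrically in |rho|).
#' @return Dosage-scale correlation matrix.
#' @export
dosage_ld <- function(maf, rho, n_terms = 50) {
  m <- length(maf)
  a <- qnorm(maf, lower.tail = FALSE)
  lat <- ar1_ld(m, rho)
  # H[k, ] = He_{k-1}(a): He_0 = 1, He_1 = a, He_j = a He_{j-1} - (j-1) He_{j-2}
  H <- matrix(0, n_terms, m)
  H[1, ] <- 1
  if (n_terms > 1) H[2, ] <- a
  if (n_terms > 2) for (k in 3:n_terms)
    H[k, ] <- a * H[k - 1, ] - (k - 2) * H[k - 2, ]
  phi <- dnorm(a)
  sdv <- sqrt(maf * (1 - maf))
  R <- matrix(0, m, m)
  fct <- cumprod(seq_len(n_terms))
  for (k in seq_len(n_terms)) {
    hk <- phi * H[k, ]
    R <- R + (lat^k / fct[k]) * outer(hk, hk)
  }
  R <- R / outer(sdv, sdv)
  diag(R) <- 1
  R <- pmin(pmax(R, -1), 1)
  (R + t(R)) / 2
}

#' Latent-scale LD matrix of one block
#'
#' The AR(1) population correlation `rho^|i-j|` the generator targets.
#' Used as the population oracle in LD-score and HEIDI tests.
#'
#' @param m Number of SNPs.
#' @param rho AR(1) parameter.
#' @return An `m x m` correlation matrix.
#' @export
ar1_ld <- function(m, rho) {
  stopifnot(m >= 1, abs(rho) < 1)
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}
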