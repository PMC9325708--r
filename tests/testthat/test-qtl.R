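# Cis windows, Haseman-Elston heritability, weight training, pQTL scans,
# clumping and pi1.

test_that("cis windows use 1-based inclusive 500 kb boundaries", {
  lay <- toy_layout()
  got <- cis_window_snps("G1", lay$genes, lay$snps)
  # gene chr1:1,000,000-1,010,000: window [500,000, 1,510,000]
  expect_true("t2" %in% got)    # BP 500,000: boundary included
  expect_false("t1" %in% got)   # BP 499,999: excluded
  expect_true("t6" %in% got)    # BP 1,510,000: upper boundary
  expect_false("t7" %in% got)   # BP 1,510,001
  expect_false("t9" %in% got)   # right position, wrong chromosome
  # brute-force enumeration over the toy positions
  manual <- lay$snps$SNP[lay$snps$CHR == "1" &
                           lay$snps$BP >= 5e5 & lay$snps$BP <= 1.51e6]
  expect_setequal(got, manual)
  expect_error(cis_window_snps("NOPE", lay$genes, lay$snps), "unknown gene")
})

test_that("Haseman-Elston recovers extreme and planted heritabilities", {
  set.seed(30)
  n <- 200
  g <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  y <- drop(scale(g[, 3]))
  est <- estimate_cis_h2(g, y)
  expect_gt(est$h2, 0.9)          # abundance = standardized cis SNP
  expect_lt(est$p, 1e-4)
  expect_error(estimate_cis_h2(g, rep(1, n)), "constant abundance")
  expect_error(estimate_cis_h2(g[1:10, ], y[1:10]), ">= 30")

  # planted h2 = 0.3 across 50 genes: mean estimate in [0.22, 0.38]
  cfg <- sim_config(seed = 31, n_blocks = 50, block_size = 20,
                    n_genes = 50, n_panel = 50, n_cohort = 500,
                    n_chrom = 5, cis_h2 = 0.3, n_covariates = 0)
  gen <- simulate_genome(cfg)
  truth <- plant_truth(gen$layout, "T1",
                       matrix(1, 1, 1, dimnames = list("T1", "T1")))
  mol <- simulate_molecular_traits(gen, truth, cfg)
  h2s <- vapply(seq_len(50), function(i) {
    cis <- cis_window_snps(gen$layout$genes$GENE[i], gen$layout$genes,
                           gen$layout$snps)
    estimate_cis_h2(gen$cohort[, cis, drop = FALSE],
                    mol$abundance[, i])$h2_raw
  }, numeric(1))
  expect_gt(mean(h2s), 0.22)
  expect_lt(mean(h2s), 0.38)
})

test_that("heritability screen has ~1% type-I rate on permuted traits", {
  set.seed(33)
  cfg <- sim_config(seed = 33, n_blocks = 2, block_size = 40, n_genes = 2,
                    n_panel = 50, n_cohort = 200, n_chrom = 2)
  gen <- simulate_genome(cfg)
  cis <- cis_window_snps("GENE0001", gen$layout$genes, gen$layout$snps)
  y <- rnorm(200)
  ps <- vapply(1:200, function(i)
    estimate_cis_h2(gen$cohort[, cis, drop = FALSE], sample(y))$p,
    numeric(1))
  expect_lt(mean(ps < 0.01), 0.04)       # close to the nominal 1%
  expect_gt(mean(ps < 0.5), 0.3)         # p roughly uniform, not degenerate
})

test_that("the heritable flag combines the p threshold and HLA exclusion", {
  st <- small_study()
  lay <- st$genome$layout
  herit <- heritability_screen(st$genome$cohort, st$abundance,
                               st$covariates, lay$genes[1:4, ], lay$snps)
  expect_true(all(herit$HERITABLE == (herit$P < 0.01 & !herit$HLA)))
  # force a gene into the exclusion window on its own chromosome
  g <- lay$genes[1, ]
  herit2 <- heritability_screen(st$genome$cohort, st$abundance,
                                st$covariates, lay$genes[1, , drop = FALSE],
                                lay$snps,
                                hla = c(g$CHR, g$START - 10, g$END + 10))
  expect_true(herit2$HLA)
  expect_false(herit2$HERITABLE)
})

test_that("weight training picks the causal SNP and drops null genes", {
  set.seed(40)
  n <- 300
  g <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  colnames(g) <- paste0("s", 1:30)
  snps <- data.frame(SNP = colnames(g), A1 = "A", A2 = "G")
  covar <- data.frame(COV1 = rnorm(n))
  y <- drop(scale(g[, 7]))
  ws <- fit_weights(g, y, covar, snps, gene = "X", seed = 2)
  expect_false(is_dropped_gene(ws))
  expect_gt(ws$cvr2, 0.95)
  top <- ws$weights$SNP[which.max(abs(ws$weights$WEIGHT))]
  expect_equal(top, "s7")

  # null genes: no model generalizes, so the gene is dropped in the large
  # majority of draws (chance out-of-fold R2 can sneak above 0)
  ys <- matrix(rnorm(n * 40), n, 40)
  drops <- vapply(1:40, function(i)
    is_dropped_gene(fit_weights(g, ys[, i], covar, snps, gene = "N",
                                seed = i)), logical(1))
  expect_gte(mean(drops), 0.5)
  d <- fit_weights(g, ys[, which(drops)[1]], covar, snps, gene = "N",
                   seed = which(drops)[1])
  expect_match(attr(d, "reason"), "CV R2")
})

test_that("predictions from trained weights track the true genetic value", {
  # two causal SNPs in LD
  cfg <- sim_config(seed = 44, n_blocks = 1, block_size = 40, n_genes = 1,
                    n_panel = 50, n_cohort = 600, n_chrom = 1, rho = 0.85)
  gen <- simulate_genome(cfg)
  xs <- pleioscan:::.std_geno(gen$cohort)
  gval <- 0.5 * xs[, 18] + 0.4 * xs[, 20]
  y <- gval + rnorm(600, 0, sqrt(1 - var(gval)))
  snps <- gen$layout$snps[, c("SNP", "A1", "A2")]
  ws <- fit_weights(gen$cohort, y, data.frame(row.names = 1:600), snps,
                    gene = "G", seed = 3)
  pred <- drop(pleioscan:::.std_geno(
    gen$cohort[, ws$weights$SNP, drop = FALSE]) %*% ws$weights$WEIGHT)
  expect_gt(cor(pred, gval), 0.9)
})

test_that("cis pQTL scan: exact fits, lead selection and planted power", {
  st <- small_study()
  lay <- st$genome$layout
  covar <- st$covariates
  # abundance equal to a genotype: p numerically 0 at that SNP
  ab <- st$abundance
  cis1 <- cis_window_snps("GENE0001", lay$genes, lay$snps)
  target <- cis1[5]
  ab[, 1] <- st$genome$cohort[, target]
  res <- cis_pqtl_scan(st$genome$cohort, ab, covar,
                       lay$genes[1, , drop = FALSE], lay$snps)
  expect_equal(res$P[res$SNP == target], 0)
  expect_true(res$LEAD[res$SNP == target])

  # planted standardized beta 0.5 at n = 500: |z| typically in [8, 16]
  set.seed(50)
  n <- 500
  g <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  colnames(g) <- paste0("s", 1:20)
  snps <- data.frame(SNP = colnames(g), CHR = "1",
                     BP = seq(1e6, by = 1e3, length.out = 20),
                     A1 = "A", A2 = "G")
  genes <- data.frame(GENE = "G1", CHR = "1", START = 1e6, END = 1.02e6)
  zs <- vapply(1:10, function(i) {
    y <- 0.5 * drop(scale(g[, 4])) + rnorm(n, 0, sqrt(0.75))
    r <- cis_pqtl_scan(g, matrix(y, dimnames = list(NULL, "G1")),
                       data.frame(C1 = rnorm(n)), genes, snps)
    abs(r$BETA[4] / r$SE[4])
  }, numeric(1))
  expect_gt(median(zs), 8)
  expect_lt(median(zs), 16)

  # rank-deficient covariates name the offending column
  expect_error(
    cis_pqtl_scan(g, matrix(rnorm(n), dimnames = list(NULL, "G1")),
                  data.frame(C1 = 1:n, C2 = 2 * (1:n)), genes, snps),
    "C2")
})

test_that("greedy clumping respects the r2 and window rules", {
  # panel where s1, s2 are in strong LD and s3 is independent
  set.seed(60)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  flip <- rbinom(n, 1, 0.1)
  s2 <- ifelse(flip == 1, sample(0:2, n, TRUE), base)
  panel <- cbind(s1 = base, s2 = s2, s3 = rbinom(n, 2, 0.4))
  r2_12 <- cor(panel[, "s1"], panel[, "s2"])^2
  expect_gt(r2_12, 0.5)

  mk_ss <- function(bp2) data.frame(
    SNP = c("s1", "s2", "s3"), CHR = "1", BP = c(1e6, bp2, 9e6),
    A1 = "A", A2 = "G", Z = c(9, 8, 7), N = 1000)
  # 100 kb apart, r2 > 0.5: the weaker hit is clumped away
  expect_equal(clump_gwas_hits(mk_ss(1.1e6), panel), c("s1", "s3"))
  # 300 kb apart: outside the 250 kb window, both retained
  expect_equal(clump_gwas_hits(mk_ss(1.3e6), panel), c("s1", "s2", "s3"))
  # no significant SNPs: empty list allowed
  ss0 <- mk_ss(1.1e6); ss0$Z <- c(1, 2, 3)
  expect_length(clump_gwas_hits(ss0, panel), 0)
})

test_that("clumping equals exhaustive greedy search on a toy block", {
  cfg <- sim_config(seed = 61, n_blocks = 1, block_size = 6, n_genes = 1,
                    n_panel = 800, n_cohort = 50, n_chrom = 1, rho = 0.9,
                    snp_spacing = 50000)
  gen <- simulate_genome(cfg)
  ss <- data.frame(SNP = gen$layout$snps$SNP, CHR = gen$layout$snps$CHR,
                   BP = gen$layout$snps$BP, A1 = gen$layout$snps$A1,
                   A2 = gen$layout$snps$A2,
                   Z = c(10, 9.5, 9, 8.5, 8, 7.5), N = 1000)
  got <- clump_gwas_hits(ss, gen$panel)
  # oracle: walk candidates by p, keep unless r2 >= 0.5 with a kept SNP
  # within 250 kb (direct re-derivation with plain loops)
  xs <- pleioscan:::.std_geno(gen$panel)
  kept <- character()
  for (i in order(-abs(ss$Z))) {
    ok <- TRUE
    for (k in kept) {
      j <- match(k, ss$SNP)
      if (abs(ss$BP[j] - ss$BP[i]) <= 250000 &&
          cor(xs[, i], xs[, j])^2 >= 0.5) ok <- FALSE
    }
    if (ok) kept <- c(kept, ss$SNP[i])
  }
  expect_equal(got, kept)
})

test_that("trans scan applies the 500 kb / different-chromosome rule", {
  st <- small_study()
  lay <- st$genome$layout
  g1 <- lay$genes[1, ]
  cis_snp <- g1$CIS_SNP
  # a SNP 400 kb from the gene: cis-flagged regardless of p
  near <- lay$snps$SNP[lay$snps$CHR == g1$CHR &
                         abs(lay$snps$BP - g1$START) < 4e5][1]
  far <- lay$snps$SNP[lay$snps$CHR != g1$CHR][1]
  ab <- st$abundance
  ab[, 1] <- st$genome$cohort[, near] + 0.5 * st$genome$cohort[, far]
  tp <- trans_pqtl_scan(c(near, far), st$genome$cohort, ab, st$covariates,
                        lay$genes[1, , drop = FALSE], lay$snps)
  expect_false(tp$TRANS[tp$SNP == near])
  expect_false(tp$SIG[tp$SNP == near])
  expect_true(tp$TRANS[tp$SNP == far])
  expect_true(tp$SIG[tp$SNP == far])   # p well below 5e-8 by construction
  expect_error(trans_pqtl_scan(character(), st$genome$cohort, ab,
                               st$covariates, lay$genes, lay$snps),
               "empty")
})

test_that("pi1 reflects the planted replication fraction", {
  expect_equal(estimate_pi1(rep(1e-10, 50))$pi1, 1)
  set.seed(70)
  expect_lt(abs(estimate_pi1(runif(1000))$pi1), 0.1)
  # 60% true signals: pi1 within +-0.15 of 0.6
  p_mix <- c(pchisq(rchisq(600, 1, ncp = 30), 1, lower.tail = FALSE),
             runif(400))
  expect_lt(abs(estimate_pi1(p_mix)$pi1 - 0.6), 0.15)
  expect_error(estimate_pi1(runif(10)), ">= 20")
})

test_that("allele flips change weight signs but not predictions or z", {
  st <- small_study()
  lay <- st$genome$layout
  g <- "GENE0002"
  cis <- cis_window_snps(g, lay$genes, lay$snps)
  geno <- st$genome$cohort[, cis, drop = FALSE]
  snps <- lay$snps[match(cis, lay$snps$SNP), c("SNP", "A1", "A2")]
  ws <- fit_weights(geno, st$abundance[, g], st$covariates, snps,
                    gene = g, seed = 5)
  # flip the first weight SNP everywhere
  fl <- ws$weights$SNP[1]
  geno2 <- geno; geno2[, fl] <- 2 - geno2[, fl]
  snps2 <- snps
  i <- match(fl, snps2$SNP)
  snps2[i, c("A1", "A2")] <- snps2[i, c("A2", "A1")]
  ws2 <- fit_weights(geno2, st$abundance[, g], st$covariates, snps2,
                     gene = g, seed = 5)
  j <- match(fl, ws2$weights$SNP)
  expect_equal(ws2$weights$WEIGHT[j],
               -ws$weights$WEIGHT[match(fl, ws$weights$SNP)],
               tolerance = 1e-6)
  expect_equal(ws2$cvr2, ws$cvr2, tolerance = 1e-6)
})
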