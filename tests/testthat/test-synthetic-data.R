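# Generator: determinism, LD structure, variance components, planted
# network excess, annotation overlap, file round-trips.

test_that("genome simulation is deterministic and validates its config", {
  cfg <- sim_config(seed = 11, n_blocks = 4, block_size = 30, n_genes = 4,
                    n_panel = 100, n_cohort = 50, n_chrom = 2)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$layout, g2$layout)

  # positions strictly increasing per chromosome; each gene on one chrom
  for (ch in unique(g1$layout$snps$CHR)) {
    bp <- g1$layout$snps$BP[g1$layout$snps$CHR == ch]
    expect_true(all(diff(bp) > 0))
  }
  expect_true(all(g1$layout$genes$START <= g1$layout$genes$END))

  expect_error(sim_config(n_panel = 1), "sample sizes")
  expect_error(sim_config(n_blocks = 0), "positive")
  expect_error(sim_config(cis_h2 = 1.2), "heritabilities")
})

test_that("latent AR(1) correlation is realized at the target rho", {
  # rho = 0: adjacent dosage correlation near zero
  cfg0 <- sim_config(seed = 3, n_blocks = 2, block_size = 40, n_genes = 2,
                     n_panel = 5000, n_cohort = 50, n_chrom = 2, rho = 0)
  g0 <- simulate_genome(cfg0)
  xs <- pleioscan:::.std_geno(g0$panel[, 1:40])
  r <- vapply(1:39, function(j) cor(xs[, j], xs[, j + 1]), numeric(1))
  expect_lt(max(abs(r)), 0.05)

  # rho = 0.9 on the latent scale, estimated back through the copula:
  # tetrachoric-style inversion via the analytic dosage-LD curve
  adj <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_blocks = 1, block_size = 30, n_genes = 1,
                      n_panel = 5000, n_cohort = 50, n_chrom = 1, rho = 0.9)
    g <- simulate_genome(cfg)
    xs <- pleioscan:::.std_geno(g$panel)
    maf <- g$layout$snps$MAF
    mean(vapply(1:29, function(j) {
      obs <- cor(xs[, j], xs[, j + 1])
      # invert the monotone latent->dosage map on a grid
      grid <- seq(0.8, 0.992, by = 0.002)
      fit <- vapply(grid, function(rl)
        dosage_ld(maf[j:(j + 1)], rl)[1, 2], numeric(1))
      grid[which.min(abs(fit - obs))]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(adj) - 0.9), 0.03)
})

test_that("generated LD matrices are positive semidefinite", {
  for (rho in c(0, 0.5, 0.8, 0.95)) {
    maf <- runif(40, 0.05, 0.5)
    ev <- eigen(dosage_ld(maf, rho), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    ev2 <- eigen(ar1_ld(40, rho), symmetric = TRUE,
                 only.values = TRUE)$values
    expect_gte(min(ev2), -1e-8)
  }
})

test_that("molecular traits realize their target cis heritability", {
  cfg <- sim_config(seed = 21, n_blocks = 50, block_size = 20,
                    n_genes = 50, n_panel = 50, n_cohort = 800,
                    n_chrom = 5, cis_h2 = 0.3, n_covariates = 0)
  gen <- simulate_genome(cfg)
  truth <- plant_truth(gen$layout, "T1",
                       matrix(1, 1, 1, dimnames = list("T1", "T1")))
  mol <- simulate_molecular_traits(gen, truth, cfg)
  xs <- pleioscan:::.std_geno(gen$cohort)
  # realized h2 = var of the true genetic value over var of the trait
  # (variance-ratio oracle; columns are z-scaled so var(y) = 1)
  h2 <- vapply(seq_len(50), function(i) {
    g <- sqrt(0.3) * xs[, gen$layout$genes$CIS_SNP[i]]
    summary(lm(mol$abundance[, i] ~ g))$r.squared
  }, numeric(1))
  expect_gt(mean(h2), 0.25)
  expect_lt(mean(h2), 0.35)
})

test_that("degenerate molecular configs behave as specified", {
  cfg0 <- sim_config(seed = 5, n_blocks = 4, block_size = 20, n_genes = 4,
                     n_panel = 50, n_cohort = 400, n_chrom = 2,
                     cis_h2 = 0, n_covariates = 0)
  gen <- simulate_genome(cfg0)
  truth <- plant_truth(gen$layout, "T1",
                       matrix(1, 1, 1, dimnames = list("T1", "T1")))
  mol <- simulate_molecular_traits(gen, truth, cfg0)
  # h2 = 0: abundance independent of genotype
  p <- vapply(1:4, function(i) {
    x <- gen$cohort[, gen$layout$genes$CIS_SNP[i]]
    summary(lm(mol$abundance[, i] ~ x))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(min(p), 0.001)  # no spurious strong association

  # h2 = 1, single causal SNP, no covariates: abundance == std genotype
  cfg1 <- sim_config(seed = 5, n_blocks = 4, block_size = 20, n_genes = 4,
                     n_panel = 50, n_cohort = 400, n_chrom = 2,
                     cis_h2 = 1, n_covariates = 0)
  mol1 <- simulate_molecular_traits(gen, truth, cfg1)
  xs <- pleioscan:::.std_geno(gen$cohort)
  g <- xs[, gen$layout$genes$CIS_SNP[1]]
  expect_gt(abs(cor(mol1$abundance[, 1], g)), 0.999999)
})

test_that("null GWAS z-scores are marginally standard normal", {
  cfg <- sim_config(seed = 13, n_blocks = 200, block_size = 100,
                    n_genes = 40, n_panel = 50, n_cohort = 50,
                    trait_h2 = 0)
  gen <- simulate_genome(cfg)
  truth <- plant_truth(gen$layout, c("T1", "T2"), diag(2))
  ss <- simulate_gwas(gen, truth, cfg, "T1")
  expect_equal(nrow(ss), 20000)
  expect_lt(abs(mean(ss$Z^2) - 1), 0.05)
  expect_error(simulate_gwas(gen, truth, cfg, "T9"), "not defined")
})

test_that("planted PPI edge excess is realized and null networks are flat", {
  universe <- sprintf("P%04d", 1:1500)
  set_a <- universe[1:400]
  set_b <- c(universe[1:13], universe[401:427])
  lay <- small_study()$genome$layout
  ratio <- function(fold, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(seed = s, ppi_q = 0.01)
      tr <- plant_truth(lay, "T1", matrix(1, 1, 1,
                                          dimnames = list("T1", "T1")),
                        ppi_fold = fold, ppi_set_a = set_a,
                        ppi_set_b = set_b)
      net <- simulate_ppi(tr, cfg, universe)
      expect_true(all(net$SYMBOL_A != net$SYMBOL_B))
      key <- paste(pmin(net$SYMBOL_A, net$SYMBOL_B),
                   pmax(net$SYMBOL_A, net$SYMBOL_B))
      expect_false(any(duplicated(key)))
      cross <- as.numeric(count_between(net, set_a, set_b))
      # unordered cross pairs: 400*40 ordered minus self-pairs of the 13
      # shared members minus the double-counted shared-shared pairs
      dens_cross <- cross / (400 * 40 - 13 - choose(13, 2))
      dens_cross / 0.01
    }, numeric(1))
  }
  expect_lt(abs(mean(ratio(1, 1:10)) - 1), 0.2)
  r25 <- mean(ratio(2.5, 11:30))
  expect_lt(abs(r25 - 2.5), 0.5)

  # q = 0: no edges at all
  cfg0 <- sim_config(seed = 2, ppi_q = 0)
  tr0 <- plant_truth(lay, "T1", matrix(1, 1, 1,
                                       dimnames = list("T1", "T1")),
                     ppi_fold = 5, ppi_set_a = set_a, ppi_set_b = set_b)
  expect_equal(nrow(simulate_ppi(tr0, cfg0, universe)), 0)
  expect_error(plant_truth(lay, "T1",
                           matrix(1, 1, 1, dimnames = list("T1", "T1")),
                           ppi_fold = -1), "ppi_fold")
})

test_that("annotation sets honor size and planted overlap", {
  universe <- sprintf("G%05d", 1:20338)
  targets <- universe[1:118]
  lay <- small_study()$genome$layout
  mk <- function(size, frac, seed = 1) {
    cfg <- sim_config(seed = seed)
    tr <- plant_truth(lay, "T1", matrix(1, 1, 1,
                                        dimnames = list("T1", "T1")),
                      annotation_sets = list(list(
                        name = "SET", size = size, targets = targets,
                        in_frac = frac)))
    simulate_annotations(tr, cfg, universe)$SET
  }
  # set = universe: every target annotated, fold exactly 1
  s_all <- mk(20338, 0)
  ev <- set_fold_enrichment(targets, s_all, 20338)
  expect_equal(ev$fold, 1)
  expect_equal(ev$k, 118)

  # planted in-set fraction 0.8, set 1137 of 20338: downstream fold
  # approximately 0.8 / (1137 / 20338)
  s <- mk(1137, 0.8)
  ev <- set_fold_enrichment(targets, s, 20338)
  expect_lt(abs(ev$fold - 0.8 / (1137 / 20338)), 0.25)

  # overlap target 0: only hypergeometric-scale overlap
  s0 <- mk(1137, 0)
  expect_lte(length(intersect(targets, s0)), 5)

  expect_error(mk(30000, 0.5), "larger than universe")
})

test_that("a study round-trips through write_study and the readers", {
  st <- small_study()
  dir <- file.path(tempdir(), "pleioscan-study")
  man <- write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, man$file))))
  back <- read_study(dir)

  expect_identical(unname(back$panel$geno),
                   unname(st$genome$panel))
  expect_identical(back$panel$snps$SNP, st$genome$layout$snps$SNP)
  expect_identical(back$panel$snps$A1, st$genome$layout$snps$A1)
  for (tr in names(st$sumstats))
    expect_equal(back$sumstats[[tr]]$Z, st$sumstats[[tr]]$Z)
  expect_equal(unname(back$abundance), unname(st$abundance),
               tolerance = 1e-12)
  expect_equal(back$genes$GENE, st$genome$layout$genes$GENE)
  expect_equal(nrow(back$ppi), nrow(st$ppi))
  expect_equal(sort(back$annotations[[1]]),
               sort(as.character(st$annotations[[1]])))
  expect_equal(back$truth$ppi_fold, st$truth$ppi_fold)
  unlink(dir, recursive = TRUE)
})

test_that("write_study with an empty trait list emits no sumstats files", {
  st <- small_study()
  st$sumstats <- list()
  dir <- file.path(tempdir(), "pleioscan-empty")
  man <- write_study(st, dir)
  expect_false(any(man$type == "sumstats"))
  back <- read_study(dir)
  expect_length(back$sumstats, 0)
  unlink(dir, recursive = TRUE)
})
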