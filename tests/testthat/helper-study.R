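# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# The standard study conditions: 20k SNPs, 200 genes, 5 traits, planted
# pleiotropy / decoys / trans links / PPI excess (heavy; built lazily).
full_study <- function() {
  .cached("full", function() {
    st <- simulate_study(sim_config(seed = 1))
    list(study = st, molecular = pipeline_molecular(st))
  })
}

# LD scores of the full study's panel (heavy; shared by LDSC tests).
full_ldscores <- function() {
  .cached("ldsc", function() {
    st <- full_study()$study
    compute_ld_scores(st$genome$panel, st$genome$layout$snps)
  })
}

# Compact study for fast end-to-end checks: 30 blocks x 40 SNPs, 10
# genes, small cohort.
small_study <- function() {
  .cached("small", function() {
    cfg <- sim_config(seed = 7, n_blocks = 30, block_size = 40,
                      n_genes = 10, n_panel = 500, n_cohort = 300,
                      n_chrom = 5, ppi_universe_size = 600)
    simulate_study(cfg)
  })
}

# One pleiotropy-null (or linkage-decoy) region for HEIDI calibration:
# strong single causal pQTL at the region center; under the null the
# trait's causal SNP coincides with it, under the decoy it is the
# adjacent SNP (latent r2 ~ 0.64 at rho = 0.8).
heidi_region_p <- function(seed, decoy = FALSE, cp_eff = 0.6,
                           cg_eff = 0.05, m = 30, rho = 0.8) {
  cg <- numeric(m); cp <- numeric(m)
  cp[m / 2] <- cp_eff
  cg[m / 2 + decoy] <- cg_eff
  r <- simulate_region(m, rho, 5e4, 500, cg, cp, seed = seed)
  pq <- data.frame(SNP = paste0("s", seq_len(m)), BETA = r$beta_pqtl,
                   SE = r$se_pqtl, P = 2 * pnorm(-abs(r$z_pqtl)),
                   stringsAsFactors = FALSE)
  top <- which.min(pq$P)
  r2 <- r$R[, top]^2
  names(r2) <- pq$SNP
  inst <- select_heidi_instruments(pq, r2, pq$SNP[top])
  if (!length(inst)) return(NA_real_)
  sel <- c(match(inst, pq$SNP), top)
  heidi_test(r$beta_gwas[sel], r$se_gwas[sel], r$beta_pqtl[sel],
             r$se_pqtl[sel], r$R[sel, sel], length(sel))$p
}

# Brute-force double-loop oracle for the between-set edge count.
brute_count_between <- function(edges, set_a, set_b,
                                count_shared_pairs = TRUE) {
  n <- 0L
  for (i in seq_len(nrow(edges))) {
    x <- edges$SYMBOL_A[i]; y <- edges$SYMBOL_B[i]
    if (x == y) next
    hit <- (x %in% set_a && y %in% set_b) || (x %in% set_b && y %in% set_a)
    if (!count_shared_pairs && all(c(x, y) %in% intersect(set_a, set_b)))
      hit <- FALSE
    n <- n + hit
  }
  n
}

# Tiny deterministic genome layout for window/boundary tests.
toy_layout <- function() {
  snps <- data.frame(
    SNP = paste0("t", 1:10), CHR = c(rep("1", 8), "2", "2"),
    BP = c(499999, 500000, 700000, 1005000, 1200000, 1510000, 1510001,
           2500000, 1005000, 600000),
    A1 = "A", A2 = "G", stringsAsFactors = FALSE
  )
  genes <- data.frame(GENE = "G1", CHR = "1", START = 1000000,
                      END = 1010000, stringsAsFactors = FALSE)
  list(snps = snps, genes = genes)
}
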