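#' Simulation configuration for a synthetic study
#'
#' Bundles every knob of the synthetic-data generator: the genome layout
#' (LD blocks, SNP spacing, genes), the three sample sizes (GWAS, LD
#' reference panel, molecular cohort), variance-component targets and the
#' PPI background density. One global `seed` fully determines all outputs;
#' each generator stage derives its own sub-seed via [sub_seed()].
#'
#' @param seed Integer global seed.
#' @param n_gwas GWAS sample size per trait (z-score scale).
#' @param n_panel LD reference-panel sample size.
#' @param n_cohort Molecular (pQTL/eQTL) cohort sample size.
#' @param n_blocks Number of independent LD blocks.
#' @param block_size SNPs per block.
#' @param n_chrom Number of chromosomes the blocks are spread over.
#' @param snp_spacing Base pairs between adjacent SNPs within a block.
#' @param block_gap Base pairs between the last SNP of one block and the
#'   first SNP of the next on the same chromosome. Defaults to 2 Mb so that
#'   cis windows (500 kb) and LD-score windows (1 Mb) never span blocks.
#' @param rho Within-block latent AR(1) correlation parameter.
#' @param maf_range Range minor-allele frequencies are drawn from.
#' @param n_genes Number of genes (at most one per block).
#' @param cis_h2 Target cis heritability per gene (scalar or per-gene).
#' @param trait_h2 Polygenic SNP heritability per GWAS trait.
#' @param n_covariates Number of molecular-cohort covariates.
#' @param covariate_var Fraction of abundance variance from covariates.
#' @param ppi_q Background PPI edge probability.
#' @param ppi_universe_size Number of symbols in the PPI universe.
#' @param ppi_physical_frac Fraction of simulated edges carrying a physical
#'   evidence type (the remainder get non-physical labels).
#' @return A list of class `pleioscan_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_gwas = 50000L,
                       n_panel = 2000L,
                       n_cohort = 500L,
                       n_blocks = 200L,
                       block_size = 100L,
                       n_chrom = 10L,
                       snp_spacing = 2000L,
                       block_gap = 2e6,
                       rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_genes = 200L,
                       cis_h2 = 0.3,
                       trait_h2 = 0.4,
                       n_covariates = 2L,
                       covariate_var = 0.05,
                       ppi_q = 0.005,
                       ppi_universe_size = 3000L,
                       ppi_physical_frac = 0.8) {
  cfg <- list(
    seed = as.integer(seed), n_gwas = n_gwas, n_panel = n_panel,
    n_cohort = n_cohort, n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), n_chrom = as.integer(n_chrom),
    snp_spacing = snp_spacing, block_gap = block_gap, rho = rho,
    maf_range = maf_range, n_genes = as.integer(n_genes), cis_h2 = cis_h2,
    trait_h2 = trait_h2, n_covariates = as.integer(n_covariates),
    covariate_var = covariate_var, ppi_q = ppi_q,
    ppi_universe_size = as.integer(ppi_universe_size),
    ppi_physical_frac = ppi_physical_frac
  )
  if (any(c(cfg$n_gwas, cfg$n_panel, cfg$n_cohort) < 2))
    stop_cfg("all sample sizes must be >= 2")
  if (cfg$n_blocks < 1 || cfg$block_size < 1)
    stop_cfg("block count and size must be positive")
  if (any(cfg$cis_h2 < 0) || any(cfg$cis_h2 > 1) ||
      any(cfg$trait_h2 < 0) || any(cfg$trait_h2 > 1))
    stop_cfg("heritabilities must lie in [0, 1]")
  if (abs(cfg$rho) >= 1) stop_cfg("rho must lie in (-1, 1)")
  if (cfg$n_genes > cfg$n_blocks)
    stop_cfg("at most one gene per LD block (n_genes <= n_blocks)")
  class(cfg) <- "pleioscan_config"
  cfg
}

#' Planted truth for a synthetic study
#'
#' Records every effect the generator plants so downstream stages can be
#' scored against it: gene-trait mediation links (pleiotropy), linkage
#' decoys (distinct causal SNPs in LD), trans SNP-gene links, the target
#' genetic-correlation matrix, the planted PPI inter-set fold and the
#' annotation in-set fractions.
#'
#' @param layout A genome layout from [simulate_genome()].
#' @param traits Character vector of trait names.
#' @param rg_matrix Symmetric target genetic-correlation matrix
#'   (unit diagonal, positive semidefinite), dimnames = traits.
#' @param pleiotropic_links data.frame `gene, trait, b_xy` — the mediation
#'   effect of gene abundance on the trait.
#' @param linkage_decoys data.frame `gene, trait, r2, gwas_beta` — a
#'   trait-causal SNP distinct from the gene's abundance-causal SNP, placed
#'   so its LD with the causal SNP is approximately `r2`.
#' @param trans_links data.frame `snp, gene, effect` — distal SNPs that
#'   regulate a gene's abundance (effect in phenotype-SD units).
#' @param ppi_fold Planted inter-set PPI edge excess.
#' @param ppi_set_a,ppi_set_b Symbol sets between which the excess is
#'   planted (may overlap).
#' @param annotation_sets List of lists with fields `name, size, targets,
#'   in_frac`: each GMT set gets `round(in_frac * length(targets))` target
#'   members plus random fill to `size`.
#' @return A list of class `pleioscan_truth`.
#' @export
plant_truth <- function(layout, traits, rg_matrix,
                        pleiotropic_links = NULL, linkage_decoys = NULL,
                        trans_links = NULL, ppi_fold = 1,
                        ppi_set_a = character(), ppi_set_b = character(),
                        annotation_sets = list()) {
  stopifnot(is.matrix(rg_matrix), nrow(rg_matrix) == length(traits))
  if (max(abs(rg_matrix - t(rg_matrix))) > 1e-12)
    stop_cfg("rg_matrix must be symmetric")
  if (max(abs(diag(rg_matrix) - 1)) > 1e-12)
    stop_cfg("rg_matrix must have unit diagonal")
  ev <- eigen(rg_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop_cfg("rg_matrix must be positive semidefinite")
  if (ppi_fold < 0) stop_cfg("ppi_fold must be >= 0")
  chk_gene <- function(g) {
    bad <- setdiff(g, layout$genes$GENE)
    if (length(bad)) stop_cfg("unknown gene(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(pleiotropic_links)) chk_gene(pleiotropic_links$gene)
  if (!is.null(linkage_decoys)) {
    chk_gene(linkage_decoys$gene)
    if (any(linkage_decoys$r2 < 0 | linkage_decoys$r2 >= 1))
      stop_cfg("decoy r2 must lie in [0, 1)")
  }
  if (!is.null(trans_links)) {
    chk_gene(trans_links$gene)
    bad <- setdiff(trans_links$snp, layout$snps$SNP)
    if (length(bad)) stop_cfg("unknown SNP(s): %s", paste(bad, collapse = ", "))
  }
  dimnames(rg_matrix) <- list(traits, traits)
  structure(list(
    traits = traits, rg_matrix = rg_matrix,
    pleiotropic_links = pleiotropic_links, linkage_decoys = linkage_decoys,
    trans_links = trans_links, ppi_fold = ppi_fold,
    ppi_set_a = ppi_set_a, ppi_set_b = ppi_set_b,
    annotation_sets = annotation_sets
  ), class = "pleioscan_truth")
}
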