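#' Default trait panel and groups for synthetic studies
#'
#' Five continuous-Z traits: two psychiatric, two neurodegenerative, one
#' brain-structure, mirroring the three trait groups the sharing summary
#' tabulates.
#'
#' @return data.frame `TRAIT GROUP`.
#' @export
default_trait_groups <- function() {
  data.frame(
    TRAIT = c("PSY1", "PSY2", "NEU1", "NEU2", "STR1"),
    GROUP = c("psychiatric", "psychiatric", "neurodegenerative",
              "neurodegenerative", "brain_structure"),
    stringsAsFactors = FALSE
  )
}

#' Default planted truth for the standard synthetic study
#'
#' The study conditions: genetic correlation 0.5 within trait groups and
#' 0.2/0.1 across; 20 pleiotropic gene-trait links at mediation effect
#' |b_xy| = 0.06 (marginal GWAS z around 7 at N = 50,000 and cis h2 0.3),
#' four of which hit one psychiatric and one neurodegenerative trait to
#' plant cross-group sharing; 10 linkage decoys at r2 = 0.7 with a strong
#' direct GWAS effect (z around 12); 3 trans links of effect 0.4 from a
#' distal chromosome; PPI sets of 400 and 40 symbols sharing 13 members
#' with planted fold 2.5; one annotation set with in-set fraction 0.8.
#'
#' @param layout Genome layout.
#' @param config A [sim_config()] object.
#' @param ppi_universe Character vector of PPI node symbols.
#' @return A [plant_truth()] object.
#' @export
default_truth <- function(layout, config, ppi_universe) {
  groups <- default_trait_groups()
  traits <- groups$TRAIT
  k <- length(traits)
  rg <- matrix(0.1, k, k, dimnames = list(traits, traits))
  same <- outer(groups$GROUP, groups$GROUP, "==")
  rg[same] <- 0.5
  rg[groups$GROUP %in% c("psychiatric", "neurodegenerative"),
     groups$GROUP %in% c("psychiatric", "neurodegenerative")] <- 0.2
  rg[same] <- 0.5
  diag(rg) <- 1

  genes <- layout$genes$GENE
  set.seed(sub_seed(config$seed, "truth"))
  sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
  if (length(genes) < 40) {
    # compact scenario for small smoke-test genomes
    np <- max(1, ceiling(length(genes) / 3))
    pl <- data.frame(gene = genes[seq_len(np)],
                     trait = rep(traits, length.out = np),
                     b_xy = 0.06 * sgn(np), stringsAsFactors = FALSE)
    nd <- min(2, length(genes) - np)
    dec <- if (nd > 0) data.frame(
      gene = genes[np + seq_len(nd)], trait = traits[seq_len(nd)],
      r2 = 0.7, gwas_beta = 12 / sqrt(config$n_gwas) * sgn(nd),
      stringsAsFactors = FALSE) else NULL
    tl <- NULL
    ti <- np + nd + 1
    if (ti <= length(genes) && config$n_chrom > 1) {
      g <- layout$genes[ti, ]
      far <- layout$blocks$BLOCK[layout$blocks$CHR != g$CHR][1]
      idx <- which(layout$snps$BLOCK == far)
      tl <- data.frame(
        snp = layout$snps$SNP[idx[ceiling(length(idx) / 4)]],
        gene = genes[ti], effect = 0.8, stringsAsFactors = FALSE)
      pl <- rbind(pl, data.frame(gene = genes[ti], trait = traits[1],
                                 b_xy = 0.1 * sgn(1)))
    }
    nu <- length(ppi_universe)
    set_a <- ppi_universe[seq_len(min(40, floor(nu / 2)))]
    set_b <- ppi_universe[c(seq_len(min(4, length(set_a))),
                            (length(set_a) + 1):min(length(set_a) + 6, nu))]
    ann <- list(list(name = "SYNAPTIC_LIKE",
                     description = "synthetic synaptic-style set",
                     size = min(50, nu - 1), targets = genes[seq_len(np)],
                     in_frac = 0.8))
    return(plant_truth(layout, traits, rg, pleiotropic_links = pl,
                       linkage_decoys = dec, trans_links = tl,
                       ppi_fold = 2.5, ppi_set_a = set_a,
                       ppi_set_b = set_b, annotation_sets = ann))
  }
  pl <- rbind(
    data.frame(gene = genes[1:4], trait = "PSY1", stringsAsFactors = FALSE),
    data.frame(gene = genes[5:8], trait = "PSY2"),
    data.frame(gene = genes[9:11], trait = "NEU1"),
    data.frame(gene = genes[12:14], trait = "NEU2"),
    data.frame(gene = genes[15:16], trait = "STR1"),
    # cross-group pleiotropy: same gene causal for a psychiatric and a
    # neurodegenerative trait
    data.frame(gene = genes[17:18], trait = c("PSY1", "PSY2")),
    data.frame(gene = genes[17:18], trait = c("NEU1", "NEU2"))
  )
  pl$b_xy <- 0.06 * sgn(nrow(pl))
  dec <- data.frame(
    gene = genes[21:30],
    trait = rep(traits, 2),
    r2 = 0.7,
    gwas_beta = 12 / sqrt(config$n_gwas) * sgn(10),
    stringsAsFactors = FALSE
  )
  # trans links: the regulating SNP sits on a different chromosome from
  # the gene (first SNP of a far block), satisfying the 5 Mb rule
  tgt <- 31:36
  far_block <- vapply(seq_along(tgt), function(k) {
    g <- layout$genes[tgt[k], ]
    cand <- layout$blocks$BLOCK[layout$blocks$CHR != g$CHR]
    cand[min(length(cand), ((k - 1) %/% 3) * 20 + 1)]
  }, numeric(1))
  # quarter-position SNP: two-sided LD neighborhood for HEIDI, distinct
  # from the resident gene's cis-causal (block-center) SNP; effect 0.8 SD
  # emulates a strong hotspot trans-pQTL
  tl <- data.frame(
    snp = vapply(far_block, function(b) {
      idx <- which(layout$snps$BLOCK == b)
      layout$snps$SNP[idx[ceiling(length(idx) / 4)]]
    }, character(1)),
    gene = genes[tgt], effect = 0.8, stringsAsFactors = FALSE
  )
  # trans genes also mediate a trait so criteria i-iii have true positives
  pl <- rbind(pl, data.frame(
    gene = genes[tgt],
    trait = c("PSY1", "NEU1", "STR1", "PSY2", "NEU2", "PSY1"),
    b_xy = 0.1 * sgn(6)))

  # PPI sets mirror the causal architecture: set A carries the
  # psychiatric-trait causal genes, set B the neurodegenerative ones,
  # overlapping in the cross-group pleiotropic genes plus shared filler
  # symbols to reach the 400 / 40 / 13-shared geometry
  psy_genes <- unique(pl$gene[pl$trait %in%
                                groups$TRAIT[groups$GROUP == "psychiatric"]])
  neu_genes <- unique(pl$gene[pl$trait %in%
                                groups$TRAIT[groups$GROUP == "neurodegenerative"]])
  both <- intersect(psy_genes, neu_genes)
  filler <- setdiff(ppi_universe, genes)
  shared_fill <- filler[seq_len(13 - length(both))]
  fill_a <- setdiff(filler, shared_fill)
  set_a <- c(psy_genes, shared_fill,
             fill_a[seq_len(400 - length(psy_genes) - length(shared_fill))])
  fill_b <- setdiff(filler, set_a)
  set_b <- c(neu_genes, shared_fill,
             fill_b[seq_len(40 - length(neu_genes) - length(shared_fill))])
  ann <- list(list(
    name = "SYNAPTIC_LIKE", description = "synthetic synaptic-style set",
    size = 300, targets = genes[1:40], in_frac = 0.8
  ))
  plant_truth(layout, traits, rg, pleiotropic_links = pl,
              linkage_decoys = dec, trans_links = tl, ppi_fold = 2.5,
              ppi_set_a = set_a, ppi_set_b = set_b, annotation_sets = ann)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator stage under one global seed: genome + genotypes,
#' planted truth, molecular cohort, per-trait GWAS summary statistics,
#' PPI network and annotation sets.
#'
#' @param config A [sim_config()] object.
#' @param truth Optional [plant_truth()] object; defaults to
#'   [default_truth()] on the generated layout.
#' @param traits Optional subset of truth traits to simulate GWAS for.
#' @param with_ppi,with_annotations Generate the network / GMT stages.
#' @return A study list: `config, genome, truth, abundance, covariates,
#'   sumstats, ppi, ppi_universe, annotations, groups`.
#' @export
simulate_study <- function(config = sim_config(), truth = NULL,
                           traits = NULL, with_ppi = TRUE,
                           with_annotations = TRUE) {
  genome <- simulate_genome(config)
  n_fill <- max(0, config$ppi_universe_size - nrow(genome$layout$genes))
  ppi_universe <- c(genome$layout$genes$GENE,
                    sprintf("PROT%05d", seq_len(n_fill)))
  if (is.null(truth)) truth <- default_truth(genome$layout, config,
                                             ppi_universe)
  mol <- simulate_molecular_traits(genome, truth, config)
  traits <- traits %||% truth$traits
  sumstats <- lapply(traits, function(tr)
    simulate_gwas(genome, truth, config, tr))
  names(sumstats) <- traits
  ppi <- if (with_ppi) simulate_ppi(truth, config, ppi_universe) else NULL
  ann <- if (with_annotations)
    simulate_annotations(truth, config, ppi_universe) else NULL
  list(
    config = config, genome = genome, truth = truth,
    abundance = mol$abundance, covariates = mol$covariates,
    sumstats = sumstats, ppi = ppi, ppi_universe = ppi_universe,
    annotations = ann, groups = default_trait_groups()
  )
}
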