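#' Simulate the molecular-trait cohort (abundance + covariates)
#'
#' Each gene's abundance is the sum of a cis genetic value (its causal cis
#' SNP scaled to the target cis heritability), any planted trans genetic
#' values, covariate effects and Gaussian noise, with the noise variance
#' chosen so the variance components sum to 1; columns are then z-scaled.
#'
#' @param genome Output of [simulate_genome()].
#' @param truth Planted truth.
#' @param config A [sim_config()] object.
#' @return List with `abundance` (n_cohort x n_genes matrix, columns named
#'   by gene) and `covariates` (n_cohort x n_covariates data.frame).
#' @export
simulate_molecular_traits <- function(genome, truth, config) {
  layout <- genome$layout
  set.seed(sub_seed(config$seed, "molecular"))
  n <- config$n_cohort
  genes <- layout$genes
  h2 <- gene_cis_h2(layout, config)
  xs <- .std_geno(genome$cohort)

  k <- config$n_covariates
  covar <- if (k > 0) matrix(rnorm(n * k), n, k) else matrix(0, n, 0)
  colnames(covar) <- if (k > 0) paste0("COV", seq_len(k)) else character()

  ab <- matrix(0, n, nrow(genes))
  colnames(ab) <- genes$GENE
  for (i in seq_len(nrow(genes))) {
    g <- genes$GENE[i]
    y <- sqrt(h2[g]) * xs[, genes$CIS_SNP[i]]
    trans_var <- 0
    tl <- truth$trans_links
    if (!is.null(tl)) {
      tl <- tl[tl$gene == g, , drop = FALSE]
      for (r in seq_len(nrow(tl))) {
        y <- y + tl$effect[r] * xs[, tl$snp[r]]
        trans_var <- trans_var + tl$effect[r]^2
      }
    }
    cov_var <- if (k > 0) config$covariate_var else 0
    if (k > 0) {
      coef <- rnorm(k, 0, sqrt(cov_var / k))
      y <- y + drop(covar %*% coef)
    }
    noise_var <- 1 - h2[g] - trans_var - cov_var
    if (noise_var < -1e-8)
      stop_cfg("variance components for gene %s exceed 1 (h2=%.2f trans=%.2f cov=%.2f)",
               g, h2[g], trans_var, cov_var)
    if (noise_var > 0) y <- y + rnorm(n, 0, sqrt(noise_var))
    ab[, i] <- y
  }
  ab <- scale(ab)
  attr(ab, "scaled:center") <- NULL
  attr(ab, "scaled:scale") <- NULL
  list(abundance = ab, covariates = as.data.frame(covar))
}

#' Simulate a PPI edge list with a planted inter-set edge excess
#'
#' Background edges appear independently with probability `q` over all
#' unordered symbol pairs; pairs with one endpoint in `truth$ppi_set_a`
#' and the other in `truth$ppi_set_b` instead appear with probability
#' `min(1, q * truth$ppi_fold)`. Each edge gets an evidence-type label
#' drawn from a physical/non-physical mix; no self-loops or duplicate
#' pairs.
#'
#' @param truth Planted truth (uses `ppi_fold`, `ppi_set_a`, `ppi_set_b`).
#' @param config A [sim_config()] object (uses `ppi_q`,
#'   `ppi_physical_frac`, seed).
#' @param universe Character vector of node symbols.
#' @return data.frame `SYMBOL_A SYMBOL_B EVIDENCE_TYPE`.
#' @export
simulate_ppi <- function(truth, config, universe) {
  if (truth$ppi_fold < 0) stop_cfg("planted PPI fold must be >= 0")
  bad <- setdiff(c(truth$ppi_set_a, truth$ppi_set_b), universe)
  if (length(bad))
    stop_cfg("PPI set members missing from universe: %s",
             paste(utils::head(bad, 5), collapse = ", "))
  set.seed(sub_seed(config$seed, "ppi"))
  u <- length(universe)
  q <- config$ppi_q
  ia <- match(truth$ppi_set_a, universe)
  ib <- match(truth$ppi_set_b, universe)

  # all unordered A-B cross pairs (shared members generate both-shared
  # pairs, which are still cross pairs)
  cross_all <- as.matrix(expand.grid(ia, ib))
  cross_all <- cbind(pmin(cross_all[, 1], cross_all[, 2]),
                     pmax(cross_all[, 1], cross_all[, 2]))
  cross_all <- unique(cross_all[cross_all[, 1] != cross_all[, 2], ,
                                drop = FALSE])
  qx <- min(1, q * truth$ppi_fold)
  cross <- cross_all[runif(nrow(cross_all)) < qx, , drop = FALSE]

  # background: Bernoulli(q) over all remaining unordered pairs, drawn as
  # a binomial edge count plus uniform distinct pair codes
  npair <- u * (u - 1) / 2
  k1 <- rbinom(1, npair, q)
  code <- sample(npair, k1) - 1
  i <- floor(((2 * u - 1) - sqrt((2 * u - 1)^2 - 8 * code)) / 2)
  # guard against floating-point edge cases in the triangular decode
  off <- code - i * (2 * u - i - 1) / 2
  fix <- off < 0
  i[fix] <- i[fix] - 1
  off[fix] <- code[fix] - i[fix] * (2 * u - i[fix] - 1) / 2
  j <- i + 1 + off
  bg <- cbind(i + 1, j + 1)
  key <- function(p) p[, 1] * (u + 1) + p[, 2]
  bg <- bg[!(key(bg) %in% key(cross_all)), , drop = FALSE]

  edges <- rbind(cross, bg)
  phys <- c("physical association", "association", "colocalization",
            "direct interaction")
  nonphys <- c("genetic interaction", "synthetic lethality")
  ne <- nrow(edges)
  is_phys <- runif(ne) < config$ppi_physical_frac
  ev <- character(ne)
  ev[is_phys] <- sample(phys, sum(is_phys), replace = TRUE)
  ev[!is_phys] <- sample(nonphys, sum(!is_phys), replace = TRUE)
  data.frame(
    SYMBOL_A = universe[edges[, 1]], SYMBOL_B = universe[edges[, 2]],
    EVIDENCE_TYPE = ev, stringsAsFactors = FALSE
  )
}

#' Simulate annotation gene sets (GMT records) with planted overlap
#'
#' Each requested set draws `round(in_frac * length(targets))` of its
#' members from the target gene list and fills the remainder uniformly
#' from the rest of the universe, so the expected in-set fraction of the
#' targets is honored.
#'
#' @param truth Planted truth (uses `annotation_sets`).
#' @param config A [sim_config()] object (seed).
#' @param universe Character vector of annotatable symbols.
#' @return Named list of character vectors (one per set), with a
#'   `description` attribute per element.
#' @export
simulate_annotations <- function(truth, config, universe) {
  set.seed(sub_seed(config$seed, "annotations"))
  out <- list()
  for (spec in truth$annotation_sets) {
    if (spec$size > length(universe))
      stop_cfg("annotation set '%s' larger than universe", spec$name)
    targets <- intersect(spec$targets, universe)
    rest <- setdiff(universe, targets)
    n_in <- min(round(spec$in_frac * length(targets)), spec$size,
                length(targets))
    # a set close to the whole universe must absorb targets regardless
    n_in <- max(n_in, spec$size - length(rest))
    members <- c(sample(targets, n_in),
                 sample(rest, spec$size - n_in))
    attr(members, "description") <- spec$description %||% spec$name
    out[[spec$name]] <- members
  }
  out
}
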