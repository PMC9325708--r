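# Molecular-cohort models: cis heritability screen (Haseman-Elston),
# predictive cis weights, cis/trans pQTL scans, GWAS-hit clumping and the
# pi1 replication statistic.

#' SNPs in a gene's cis window
#'
#' The cis window spans `[start - window, end + window]` (1-based,
#' inclusive) on the gene's chromosome; the default window is 500 kb.
#'
#' @param gene Gene symbol.
#' @param genes Gene-coordinate data.frame `GENE CHR START END`.
#' @param snps SNP data.frame `SNP CHR BP`.
#' @param window Window half-width in bp.
#' @return Character vector of SNP ids.
#' @export
cis_window_snps <- function(gene, genes, snps, window = 5e5) {
  g <- genes[genes$GENE == gene, ]
  if (nrow(g) != 1) stop_cfg("unknown gene '%s'", gene)
  snps$SNP[snps$CHR == g$CHR & snps$BP >= g$START - window &
             snps$BP <= g$END + window]
}

# distance from SNPs to a gene's nearest boundary (0 inside; Inf on a
# different chromosome)
.gene_dist <- function(gene_row, chr, bp) {
  d <- pmax(0, pmax(gene_row$START - bp, bp - gene_row$END))
  d[chr != gene_row$CHR] <- Inf
  d
}

# residualize columns of m on covariates (with intercept) via QR;
# errors name the offending column on rank deficiency
.resid_covar <- function(m, covariates) {
  cv <- as.matrix(cbind(`(Intercept)` = 1, covariates))
  qrd <- qr(cv)
  if (qrd$rank < ncol(cv)) {
    bad <- colnames(cv)[qrd$pivot[(qrd$rank + 1):ncol(cv)]]
    stop_cfg("rank-deficient covariates: %s", paste(bad, collapse = ", "))
  }
  m <- as.matrix(m)
  m - qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE] %*%
    crossprod(qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE], m)
}

#' Genotype principal components of the molecular cohort
#'
#' @param geno Cohort dosage matrix.
#' @param k Number of components (default 10).
#' @return n x k matrix of PC scores, columns `PC1..PCk`.
#' @export
genotype_pcs <- function(geno, k = 10) {
  xs <- .std_geno(geno)
  K <- tcrossprod(xs) / ncol(xs)
  es <- eigen(K, symmetric = TRUE)
  k <- min(k, sum(es$values > 1e-12))
  sc <- es$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(es$values[seq_len(k)]), k)
  colnames(sc) <- paste0("PC", seq_len(k))
  sc
}

#' Cis SNP heritability of one gene by Haseman-Elston regression
#'
#' Regresses phenotype cross-products y_i y_j (i < j) on the cis genetic
#' relationship matrix entries; the slope estimates the cis h2 of the
#' (standardized) abundance. The p-value is one-sided from a
#' jackknife-over-samples standard error. The reported h2 is clamped to
#' [0, 1]; the raw slope is retained.
#'
#' @param geno_cis Cohort dosages over the gene's cis SNPs.
#' @param y Abundance vector.
#' @param covariates Optional covariate data.frame/matrix to residualize
#'   out first.
#' @param n_jack Number of sample-jackknife blocks (default 100).
#' @return List `h2, h2_raw, se, p, n_snp`.
#' @export
estimate_cis_h2 <- function(geno_cis, y, covariates = NULL, n_jack = 100) {
  n <- length(y)
  if (n < 30) stop_cfg("need >= 30 cohort samples")
  if (sd(y) == 0) stop_cfg("constant abundance")
  geno_cis <- as.matrix(geno_cis)
  if (ncol(geno_cis) < 1) stop_cfg("gene has no cis SNPs")
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0)
    y <- drop(.resid_covar(matrix(y), covariates))
  y <- (y - mean(y)) / sd(y)
  xs <- .std_geno(geno_cis)
  G <- tcrossprod(xs) / ncol(xs)
  P <- tcrossprod(y)
  diag(G) <- 0; diag(P) <- 0
  ones <- matrix(1, n, n); diag(ones) <- 0

  mats <- list(n = ones, g = G, p = P, gg = G * G, gp = G * P)
  rs <- vapply(mats, rowSums, numeric(n))
  tot <- colSums(rs) / 2

  slope_of <- function(s) {
    den <- s["n"] * s["gg"] - s["g"]^2
    (s["n"] * s["gp"] - s["g"] * s["p"]) / den
  }
  h2 <- unname(slope_of(tot))

  n_jack <- min(n_jack, n)
  blk <- ceiling(seq_len(n) / (n / n_jack))
  loo <- vapply(seq_len(max(blk)), function(b) {
    i <- which(blk == b)
    within <- vapply(mats, function(m)
      sum(m[i, i, drop = FALSE]) / 2, numeric(1))
    touching <- colSums(rs[i, , drop = FALSE]) - within
    slope_of(tot - touching)
  }, numeric(1))
  se <- .jack_se(loo)
  zstat <- h2 / se
  list(h2 = min(max(h2, 0), 1), h2_raw = h2, se = se,
       p = pnorm(zstat, lower.tail = FALSE), n_snp = ncol(geno_cis))
}

#' Screen all genes for cis heritability
#'
#' Applies [estimate_cis_h2()] per gene and flags heritable genes
#' (p < `p_cut` and outside the HLA exclusion region, by default
#' chr6:25-34 Mb).
#'
#' @param geno Cohort dosage matrix (all SNPs).
#' @param abundance Abundance matrix (samples x genes).
#' @param covariates Covariate table.
#' @param genes,snps Layout data.frames.
#' @param window Cis window in bp.
#' @param p_cut Heritability p threshold (default 0.01).
#' @param hla c(chr, start, end) exclusion region.
#' @param n_jack Jackknife blocks.
#' @return data.frame `GENE H2 H2_RAW SE P N_SNP HLA HERITABLE`.
#' @export
heritability_screen <- function(geno, abundance, covariates, genes, snps,
                                window = 5e5, p_cut = 0.01,
                                hla = c("6", 25e6, 34e6), n_jack = 100) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$GENE[i]
    cis <- cis_window_snps(g, genes, snps, window)
    if (!length(cis)) return(NULL)
    est <- estimate_cis_h2(geno[, cis, drop = FALSE], abundance[, g],
                           covariates, n_jack = n_jack)
    in_hla <- genes$CHR[i] == hla[1] &
      genes$END[i] >= as.numeric(hla[2]) &
      genes$START[i] <= as.numeric(hla[3])
    data.frame(GENE = g, H2 = est$h2, H2_RAW = est$h2_raw, SE = est$se,
               P = est$p, N_SNP = est$n_snp, HLA = in_hla,
               HERITABLE = est$p < p_cut && !in_hla,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train predictive cis weights for one gene
#'
#' Fits four models on covariate-residualized data — marginal top-SNP,
#' ridge, lasso and elastic net (alpha = 0.5) — and keeps the weights of
#' the model with the best 5-fold cross-validated R2 (shared fold
#' assignment, deterministic given `seed`). Genes where no model achieves
#' positive CV R2 are dropped (NULL with a `reason` attribute).
#'
#' @param geno_cis Cohort dosages over the cis SNPs (columns named).
#' @param y Abundance vector.
#' @param covariates Covariate table.
#' @param snps SNP data.frame `SNP A1 A2` (alleles recorded with weights).
#' @param gene Gene symbol (metadata).
#' @param seed Fold-assignment seed.
#' @param nfolds Cross-validation folds.
#' @return List `gene, weights` (data.frame `SNP A1 A2 WEIGHT`, nonzero
#'   rows only), `model`, `cvr2`; or a `dropped_gene` object (see
#'   [is_dropped_gene()]) carrying the reason as an attribute.
#' @export
fit_weights <- function(geno_cis, y, covariates, snps, gene = "",
                        seed = 1L, nfolds = 5) {
  x <- .resid_covar(geno_cis, covariates)
  y <- drop(.resid_covar(matrix(y), covariates))
  n <- length(y)
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  sst <- sum((y - mean(y))^2)

  # top-SNP: per-fold marginal scan + OLS on the winning SNP
  sse_top <- 0
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    xt <- x[tr, , drop = FALSE]; yt <- y[tr]
    xc <- sweep(xt, 2, colMeans(xt))
    sxx <- colSums(xc^2)
    b <- drop(crossprod(xc, yt - mean(yt))) / pmax(sxx, 1e-12)
    r2m <- b^2 * sxx
    j <- which.max(r2m)
    pred <- mean(yt) + (x[!tr, j] - mean(xt[, j])) * b[j]
    sse_top <- sse_top + sum((y[!tr] - pred)^2)
  }
  cv <- c(top = 1 - sse_top / sst)

  fits <- list()
  for (alpha in c(ridge = 0, lasso = 1, enet = 0.5)) {
    nm <- names(which(c(ridge = 0, lasso = 1, enet = 0.5) == alpha))[1]
    fit <- tryCatch(
      glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                        standardize = TRUE, nlambda = 50),
      error = function(e) NULL)
    if (is.null(fit)) { cv[nm] <- -Inf; next }
    cv[nm] <- 1 - min(fit$cvm) / (sst / n)
    fits[[nm]] <- fit
  }

  # winners in decreasing CV R2; a positive-CV lasso can still shrink
  # everything to zero at lambda.min, in which case the next model wins
  for (winner in names(sort(cv, decreasing = TRUE))) {
    if (cv[winner] <= 0) break
    if (winner == "top") {
      xc <- sweep(x, 2, colMeans(x))
      sxx <- colSums(xc^2)
      b <- drop(crossprod(xc, y - mean(y))) / pmax(sxx, 1e-12)
      j <- which.max(b^2 * sxx)
      w <- numeric(ncol(x)); w[j] <- b[j]
    } else {
      w <- drop(coef(fits[[winner]], s = "lambda.min"))[-1]
    }
    nz <- which(w != 0)
    if (!length(nz)) next
    ids <- colnames(geno_cis)[nz]
    i <- match(ids, snps$SNP)
    return(list(
      gene = gene,
      weights = data.frame(SNP = ids, A1 = snps$A1[i], A2 = snps$A2[i],
                           WEIGHT = w[nz], stringsAsFactors = FALSE),
      model = winner, cvr2 = unname(cv[winner])
    ))
  }
  structure(list(), class = "dropped_gene",
            reason = sprintf("no model with positive CV R2 (best %.3f)",
                             max(cv)))
}

#' @rdname fit_weights
#' @param x Object to test.
#' @export
is_dropped_gene <- function(x) inherits(x, "dropped_gene")

# marginal OLS of y on each column of x, both already
# covariate-residualized; df accounts for the covariates removed
.marginal_ols <- function(x, y, df) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  b <- sxy / pmax(sxx, 1e-12)
  sse <- pmax(sum(yc^2) - b * sxy, 0)
  se <- sqrt(sse / df / pmax(sxx, 1e-12))
  tt <- ifelse(se > 0, b / se, 0)
  p <- 2 * pt(-abs(tt), df)
  p[se == 0 & b != 0] <- 0
  data.frame(BETA = b, SE = se, P = p)
}

#' Cis pQTL scan
#'
#' Per-SNP ordinary least squares of abundance on dosage within each
#' gene's cis window, adjusting for the supplied covariates (which should
#' include the genotype principal components). The lead pQTL per gene is
#' the minimum-p SNP, ties broken by smaller position.
#'
#' @param geno Cohort dosage matrix.
#' @param abundance Abundance matrix (samples x genes).
#' @param covariates Covariate table (e.g. PCs from [genotype_pcs()]).
#' @param genes,snps Layout data.frames.
#' @param window Cis window in bp (default 500 kb).
#' @return data.frame `GENE SNP CHR BP BETA SE P DIST CIS LEAD`.
#' @export
cis_pqtl_scan <- function(geno, abundance, covariates, genes, snps,
                          window = 5e5) {
  xr <- .resid_covar(geno, covariates)
  yr <- .resid_covar(abundance, covariates)
  df <- nrow(xr) - ncol(as.matrix(covariates)) - 2
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes$GENE[i]
    cis <- cis_window_snps(g, genes, snps, window)
    if (!length(cis)) next
    si <- match(cis, snps$SNP)
    res <- .marginal_ols(xr[, cis, drop = FALSE], yr[, g], df)
    res$GENE <- g
    res$SNP <- cis
    res$CHR <- snps$CHR[si]
    res$BP <- snps$BP[si]
    res$DIST <- .gene_dist(genes[i, ], res$CHR, res$BP)
    res$CIS <- res$DIST <= window
    ord <- order(res$P, res$BP)
    res$LEAD <- FALSE
    res$LEAD[ord[1]] <- TRUE
    out[[i]] <- res[, c("GENE", "SNP", "CHR", "BP", "BETA", "SE", "P",
                        "DIST", "CIS", "LEAD")]
  }
  do.call(rbind, out)
}

#' Greedy LD clumping of GWAS hits
#'
#' Sorts genome-wide-significant SNPs by p and keeps a SNP unless its r2
#' with an already-kept SNP within `window_kb` reaches `r2_cut`.
#'
#' @param ss Sumstats (`SNP CHR BP Z`).
#' @param panel Panel dosage matrix (columns named by SNP).
#' @param p_cut Significance threshold (default 5e-8).
#' @param r2_cut r2 threshold (default 0.5).
#' @param window_kb Clumping window in kb (default 250).
#' @return Character vector of retained SNP ids (possibly empty).
#' @export
clump_gwas_hits <- function(ss, panel, p_cut = 5e-8, r2_cut = 0.5,
                            window_kb = 250) {
  p <- 2 * pnorm(-abs(ss$Z))
  hits <- ss[p < p_cut, , drop = FALSE]
  hits$P <- p[p < p_cut]
  if (!nrow(hits)) return(character())
  hits <- hits[order(hits$P, hits$BP), ]
  kept <- integer()
  xs <- .std_geno(panel[, hits$SNP, drop = FALSE])
  win <- window_kb * 1000
  for (i in seq_len(nrow(hits))) {
    near <- kept[hits$CHR[kept] == hits$CHR[i] &
                   abs(hits$BP[kept] - hits$BP[i]) <= win]
    if (length(near)) {
      r2 <- drop(crossprod(xs[, near, drop = FALSE],
                           xs[, i]))^2 / (nrow(xs) - 1)^2
      if (any(r2 >= r2_cut)) next
    }
    kept <- c(kept, i)
  }
  hits$SNP[kept]
}

#' Trans pQTL scan over clumped GWAS hits
#'
#' Tests every supplied SNP against every gene's abundance (OLS adjusting
#' for covariates). Records are flagged trans when the SNP lies more than
#' `window` bp outside the gene (or on another chromosome), and
#' significant at `p_cut`.
#'
#' @param snp_ids SNPs to test (e.g. from [clump_gwas_hits()]).
#' @param geno,abundance,covariates As in [cis_pqtl_scan()].
#' @param genes,snps Layout data.frames.
#' @param window Cis/trans distance threshold in bp (default 500 kb).
#' @param p_cut Trans-pQTL significance threshold (default 5e-8).
#' @return data.frame `GENE SNP CHR BP BETA SE P DIST TRANS SIG`.
#' @export
trans_pqtl_scan <- function(snp_ids, geno, abundance, covariates, genes,
                            snps, window = 5e5, p_cut = 5e-8) {
  if (!length(snp_ids)) stop_cfg("empty clumped SNP list")
  xr <- .resid_covar(geno[, snp_ids, drop = FALSE], covariates)
  yr <- .resid_covar(abundance[, genes$GENE, drop = FALSE], covariates)
  df <- nrow(xr) - ncol(as.matrix(covariates)) - 2
  si <- match(snp_ids, snps$SNP)
  out <- vector("list", length(snp_ids))
  for (k in seq_along(snp_ids)) {
    xc <- xr[, k] - mean(xr[, k])
    sxx <- sum(xc^2)
    yc <- sweep(yr, 2, colMeans(yr))
    sxy <- drop(crossprod(yc, xc))
    b <- sxy / sxx
    sse <- pmax(colSums(yc^2) - b * sxy, 0)
    se <- sqrt(sse / df / sxx)
    tt <- ifelse(se > 0, b / se, 0)
    p <- 2 * pt(-abs(tt), df)
    d <- vapply(seq_len(nrow(genes)), function(i)
      .gene_dist(genes[i, ], snps$CHR[si[k]], snps$BP[si[k]]), numeric(1))
    out[[k]] <- data.frame(
      GENE = genes$GENE, SNP = snp_ids[k], CHR = snps$CHR[si[k]],
      BP = snps$BP[si[k]], BETA = b, SE = se, P = p, DIST = d,
      TRANS = d > window, SIG = p < p_cut & d > window,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Storey-style pi1 replication statistic
#'
#' `pi1 = 1 - pi0` with `pi0 = #\{p > lambda\} / ((1 - lambda) m)` at a
#' single lambda (default 0.5), capped to [0, 1]. Quantifies the fraction
#' of lead pQTLs that replicate in an independent dataset.
#'
#' @param p Replication p-values of the lead pQTLs.
#' @param lambda Tail cutoff (default 0.5).
#' @return List `pi1, pi0, lambda, m`.
#' @export
estimate_pi1 <- function(p, lambda = 0.5) {
  if (length(p) < 20) stop_cfg("need >= 20 p-values for pi1")
  pi0 <- sum(p > lambda) / ((1 - lambda) * length(p))
  pi0 <- min(max(pi0, 0), 1)
  list(pi1 = 1 - pi0, pi0 = pi0, lambda = lambda, m = length(p))
}
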