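# Decision rules that turn XWAS + SMR/HEIDI + COLOC evidence into causal
# calls, sharing tabulation across trait groups, and the genetic
# correlation vs sharing relationship.

#' Pipeline decision thresholds
#'
#' @param xwas_fdr XWAS FDR p cutoff (default 0.05).
#' @param smr_p SMR p cutoff (default 0.05).
#' @param heidi_p HEIDI p cutoff — calls require p above it (default
#'   0.05).
#' @param pp4 COLOC PP4 cutoff (default 0.5).
#' @param gwas_p Genome-wide significance (default 5e-8).
#' @param h2_p Heritability screen p (default 0.01).
#' @param trans_rule `"bonferroni"` (default) or `"fdr"` for trans-SMR
#'   multiplicity.
#' @return List of class `pleioscan_thresholds`.
#' @export
pipeline_thresholds <- function(xwas_fdr = 0.05, smr_p = 0.05,
                                heidi_p = 0.05, pp4 = 0.5, gwas_p = 5e-8,
                                h2_p = 0.01,
                                trans_rule = c("bonferroni", "fdr")) {
  vals <- c(xwas_fdr, smr_p, heidi_p, pp4, gwas_p, h2_p)
  if (any(vals <= 0 | vals >= 1)) stop_cfg("all cutoffs must lie in (0, 1)")
  structure(list(xwas_fdr = xwas_fdr, smr_p = smr_p, heidi_p = heidi_p,
                 pp4 = pp4, gwas_p = gwas_p, h2_p = h2_p,
                 trans_rule = match.arg(trans_rule)),
            class = "pleioscan_thresholds")
}

#' Call a cis-regulated gene causal (or not) for one trait
#'
#' A gene has evidence consistent with causality or pleiotropy when
#' either (route SMR_HEIDI) its XWAS FDR p, SMR p and HEIDI p satisfy
#' the A-C criteria, or (route COLOC) its XWAS FDR p and PP4 satisfy the
#' D-E criteria; BOTH when both routes hold. The XWAS FDR gate is shared
#' by the two routes. A gene whose HEIDI test was skipped can qualify
#' only via COLOC.
#'
#' @param xwas_fdr XWAS FDR-adjusted p.
#' @param smr_p,heidi_p SMR and HEIDI p (NA when unavailable/skipped).
#' @param pp4 COLOC PP4 (NA when unavailable).
#' @param thresholds A [pipeline_thresholds()] object.
#' @return Route string `"SMR_HEIDI"`, `"COLOC"`, `"BOTH"`, or NULL (no
#'   call).
#' @export
call_cis_causal <- function(xwas_fdr, smr_p = NA, heidi_p = NA, pp4 = NA,
                            thresholds = pipeline_thresholds()) {
  if (is.na(smr_p) && is.na(pp4))
    stop_cfg("need at least one of SMR and COLOC records to evaluate")
  th <- thresholds
  gate <- xwas_fdr < th$xwas_fdr
  smr_route <- gate && !is.na(smr_p) && smr_p < th$smr_p &&
    !is.na(heidi_p) && heidi_p > th$heidi_p
  coloc_route <- gate && !is.na(pp4) && pp4 > th$pp4
  if (smr_route && coloc_route) return("BOTH")
  if (smr_route) return("SMR_HEIDI")
  if (coloc_route) return("COLOC")
  NULL
}

#' Call a trans-regulated gene causal (or not) for one trait
#'
#' Requires (i) a trans-pQTL association at genome-wide significance,
#' (ii) a trans-SMR result passing the configured multiplicity rule, and
#' (iii) HEIDI p above the cutoff.
#'
#' @param pqtl_p Trans-pQTL association p.
#' @param smr_pass Logical: trans-SMR passed the multiplicity rule (see
#'   [trans_smr_pass()]).
#' @param heidi_p HEIDI p (NA fails the criterion).
#' @param thresholds A [pipeline_thresholds()] object.
#' @return `"TRANS"` or NULL.
#' @export
call_trans_causal <- function(pqtl_p, smr_pass, heidi_p,
                              thresholds = pipeline_thresholds()) {
  th <- thresholds
  ok <- pqtl_p < th$gwas_p && isTRUE(smr_pass) && !is.na(heidi_p) &&
    heidi_p > th$heidi_p
  if (ok) "TRANS" else NULL
}

#' Tabulate causal-gene sharing within and between trait groups
#'
#' For each trait t and group G, the shared percentage is
#' `100 |{genes causal for t and for >= 1 other trait in G}| /
#' |{genes causal for t}|` (within-group sharing excludes t itself).
#' Cross-group shared sets are the genes causal for at least one trait in
#' each of the two groups. Traits with zero calls get a dash row.
#' Duplicate call records are ignored.
#'
#' @param calls data.frame `GENE TRAIT MODE` (one row per call; MODE cis
#'   or trans).
#' @param groups data.frame `TRAIT GROUP`.
#' @return List `per_trait` (counts + percentage columns per group, "-"
#'   where undefined), `shared` (named list of cross/within-group shared
#'   gene vectors, names `groupA|groupB`).
#' @export
tabulate_sharing <- function(calls, groups) {
  stopifnot(all(c("GENE", "TRAIT", "MODE") %in% names(calls)))
  if (!all(calls$TRAIT %in% groups$TRAIT))
    stop_cfg("calls contain traits missing from the group map")
  calls <- unique(calls[, c("GENE", "TRAIT", "MODE")])
  gsets <- split(calls$GENE, calls$TRAIT)
  gnames <- unique(groups$GROUP)

  per_trait <- lapply(groups$TRAIT, function(t) {
    mine <- calls[calls$TRAIT == t, ]
    cis <- length(unique(mine$GENE[mine$MODE == "cis"]))
    trans <- length(unique(mine$GENE[mine$MODE == "trans"]))
    tot <- length(unique(mine$GENE))
    row <- data.frame(TRAIT = t, CIS = cis, TRANS = trans, TOTAL = tot,
                      stringsAsFactors = FALSE)
    for (g in gnames) {
      others <- setdiff(groups$TRAIT[groups$GROUP == g], t)
      col <- paste0("SHARED_", toupper(g))
      if (tot == 0) { row[[col]] <- "-"; next }
      other_genes <- unique(unlist(gsets[intersect(others, names(gsets))]))
      shared <- length(intersect(unique(mine$GENE), other_genes))
      row[[col]] <- sprintf("%.0f%%", 100 * shared / tot)
    }
    row
  })
  per_trait <- do.call(rbind, per_trait)

  shared <- list()
  for (i in seq_along(gnames)) for (j in i:length(gnames)) {
    ta <- groups$TRAIT[groups$GROUP == gnames[i]]
    tb <- groups$TRAIT[groups$GROUP == gnames[j]]
    ga <- unique(unlist(gsets[intersect(ta, names(gsets))]))
    gb <- unique(unlist(gsets[intersect(tb, names(gsets))]))
    if (i == j) {
      # within-group: genes causal for >= 2 traits of the group
      cnt <- table(unique(calls[calls$TRAIT %in% ta,
                                c("GENE", "TRAIT")])$GENE)
      sh <- names(cnt)[cnt >= 2]
    } else sh <- intersect(ga, gb)
    shared[[paste(gnames[i], gnames[j], sep = "|")]] <- sort(sh)
  }
  list(per_trait = per_trait, shared = shared)
}

#' Correlate genetic correlation with causal-gene sharing
#'
#' One observation per cross-group trait pair: the pair's estimated rg
#' against its sharing percentage, defined (by default) as
#' `100 |causal(t1) intersect causal(t2)| / |causal(t2)|` with t2 the
#' second group's trait; Spearman rank correlation with exact p for
#' n < 10.
#'
#' @param rg_tab data.frame `TRAIT1 TRAIT2 RG` (either order).
#' @param calls Calls data.frame (`GENE TRAIT`).
#' @param groups Group map.
#' @param group_pair Character vector of two group labels.
#' @param denominator `"second"` (default) or `"first"`: whose causal set
#'   sizes the percentage.
#' @return List `rho, p, n_pairs, data` (the paired observations).
#' @export
correlate_rg_sharing <- function(rg_tab, calls, groups, group_pair,
                                 denominator = c("second", "first")) {
  denominator <- match.arg(denominator)
  t1s <- groups$TRAIT[groups$GROUP == group_pair[1]]
  t2s <- groups$TRAIT[groups$GROUP == group_pair[2]]
  gsets <- split(unique(calls[, c("GENE", "TRAIT")])$GENE,
                 unique(calls[, c("GENE", "TRAIT")])$TRAIT)
  obs <- list()
  for (a in t1s) for (b in t2s) {
    hit <- rg_tab[(rg_tab$TRAIT1 == a & rg_tab$TRAIT2 == b) |
                    (rg_tab$TRAIT1 == b & rg_tab$TRAIT2 == a), ]
    if (!nrow(hit)) next
    den_set <- if (denominator == "second") gsets[[b]] else gsets[[a]]
    if (is.null(den_set) || !length(den_set)) next
    sh <- 100 * length(intersect(gsets[[a]], gsets[[b]])) / length(den_set)
    obs[[length(obs) + 1]] <- data.frame(
      TRAIT1 = a, TRAIT2 = b, RG = hit$RG[1], SHARED_PCT = sh,
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs)
  if (is.null(obs) || nrow(obs) < 4)
    stop_cfg("fewer than 4 trait pairs with both rg and sharing defined")
  ct <- suppressWarnings(cor.test(obs$RG, obs$SHARED_PCT,
                                  method = "spearman",
                                  exact = nrow(obs) < 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(obs),
       data = obs)
}
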