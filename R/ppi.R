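# Constrained bootstrap test for excess physical PPIs between two
# causal-gene sets, plus fold/hypergeometric enrichment against
# annotation sets.

PHYSICAL_EVIDENCE <- c("physical association", "association",
                       "colocalization", "direct interaction")

#' Keep only physical protein-protein interactions
#'
#' Retains edges whose evidence label is one of the four physical
#' categories (physical association, association, colocalization, direct
#' interaction); unknown labels trigger a warning and are dropped.
#'
#' @param edges data.frame `SYMBOL_A SYMBOL_B EVIDENCE_TYPE`.
#' @param vocabulary Known evidence labels (physical + non-physical).
#' @return Filtered edge data.frame with attribute `n_removed`.
#' @export
filter_physical <- function(edges,
                            vocabulary = c(PHYSICAL_EVIDENCE,
                                           "genetic interaction",
                                           "synthetic lethality")) {
  unknown <- !(edges$EVIDENCE_TYPE %in% vocabulary)
  if (any(unknown))
    warning(sprintf("%d edge(s) with unknown evidence label dropped",
                    sum(unknown)))
  keep <- edges$EVIDENCE_TYPE %in% PHYSICAL_EVIDENCE
  out <- edges[keep & !unknown, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep | unknown)
  out
}

#' Count edges between two gene sets
#'
#' An edge counts iff one endpoint is in `set_a` and the other in
#' `set_b`; edges internal to one set's exclusive members do not count;
#' members shared between the sets may sit on either side. Each unordered
#' edge counts once; edges between two shared members count once (or not
#' at all with `count_shared_pairs = FALSE`).
#'
#' @param edges Edge data.frame (`SYMBOL_A SYMBOL_B`).
#' @param set_a,set_b Character gene sets (nonempty).
#' @param count_shared_pairs Count edges whose endpoints are both in
#'   `set_a` and `set_b` (default TRUE).
#' @return Integer count with the contributing edges attached as
#'   attribute `edges`.
#' @export
count_between <- function(edges, set_a, set_b, count_shared_pairs = TRUE) {
  if (!length(set_a) || !length(set_b)) stop_cfg("gene sets must be nonempty")
  a1 <- edges$SYMBOL_A %in% set_a
  b1 <- edges$SYMBOL_A %in% set_b
  a2 <- edges$SYMBOL_B %in% set_a
  b2 <- edges$SYMBOL_B %in% set_b
  cross <- (a1 & b2) | (b1 & a2)
  both_shared <- (a1 & b1) & (a2 & b2)
  keep <- if (count_shared_pairs) cross else cross & !both_shared
  keep <- keep & edges$SYMBOL_A != edges$SYMBOL_B
  s0 <- sum(keep)
  attr(s0, "edges") <- edges[keep, , drop = FALSE]
  s0
}

#' Constrained bootstrap null for the between-set edge count
#'
#' Each iteration draws `n_a + n_b - n_shared` distinct symbols uniformly
#' from the network's node universe, assigns `n_shared` of them to both
#' sets, `n_a - n_shared` to A only and `n_b - n_shared` to B only, and
#' records the between-set edge count. Deterministic given `seed`.
#'
#' @param edges Edge data.frame (already filtered to physical edges).
#' @param n_a,n_b,n_shared Set sizes and overlap to preserve.
#' @param n_iter Number of bootstrap iterations.
#' @param seed Integer seed.
#' @param universe Node universe to sample from; defaults to all symbols
#'   present in the network.
#' @param count_shared_pairs Passed through to the edge count.
#' @return Integer vector of null counts (length `n_iter`).
#' @export
bootstrap_null <- function(edges, n_a, n_b, n_shared, n_iter = 10000,
                           seed = 1L, universe = NULL,
                           count_shared_pairs = TRUE) {
  if (n_shared > min(n_a, n_b)) stop_cfg("n_shared exceeds a set size")
  # the count is symmetric in the two sets; canonicalize so that swapping
  # the set labels reproduces the identical null draws
  if (n_b > n_a) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  universe <- universe %||% unique(c(edges$SYMBOL_A, edges$SYMBOL_B))
  need <- n_a + n_b - n_shared
  if (need > length(universe))
    stop_cfg("universe of %d nodes too small for %d distinct draws",
             length(universe), need)
  set.seed(seed)
  ia <- match(edges$SYMBOL_A, universe)
  ib <- match(edges$SYMBOL_B, universe)
  ok <- !is.na(ia) & !is.na(ib) & ia != ib
  ia <- ia[ok]; ib <- ib[ok]
  u <- length(universe)
  vapply(seq_len(n_iter), function(it) {
    pick <- sample.int(u, need)
    inA <- inB <- logical(u)
    inA[pick[seq_len(n_a)]] <- TRUE
    inB[pick[c(seq_len(n_shared), (n_a + 1):need)]] <- TRUE
    cross <- (inA[ia] & inB[ib]) | (inB[ia] & inA[ib])
    if (!count_shared_pairs)
      cross <- cross & !(inA[ia] & inB[ia] & inA[ib] & inB[ib])
    sum(cross)
  }, numeric(1))
}

#' Empirical bootstrap p-value and fold
#'
#' Exactly `p = (1 + sum(I(s_i >= s0))) / (N + 1)` with ties counted in
#' the tail; `fold = s0 / mean(null)` (infinite, with a flag, when the
#' null mean is zero).
#'
#' @param s0 Observed between-set count.
#' @param null_counts Null counts from [bootstrap_null()].
#' @return List `p, fold, s0, n_iter, null_mean, fold_infinite`.
#' @export
empirical_p <- function(s0, null_counts) {
  n <- length(null_counts)
  if (n < 1) stop_cfg("need at least one null count")
  p <- (1 + sum(null_counts >= s0)) / (n + 1)
  mu <- mean(null_counts)
  list(p = p, fold = if (mu > 0) s0 / mu else Inf, s0 = s0, n_iter = n,
       null_mean = mu, fold_infinite = mu == 0)
}

#' Full PPI bootstrap enrichment between two causal-gene sets
#'
#' Filters the network to physical edges, drops set members absent from
#' the network (logging how many), counts the observed between-set edges
#' and compares them with the constrained bootstrap null.
#'
#' @param edges Raw edge data.frame (`SYMBOL_A SYMBOL_B EVIDENCE_TYPE`).
#' @param set_a,set_b Causal-gene sets.
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param count_shared_pairs Convention for both-shared edges.
#' @return List: `s0, p, fold, null_mean, n_iter, n_a, n_b, n_shared,
#'   dropped_a, dropped_b, edges` (the contributing edge list), `seed`.
#' @export
ppi_bootstrap_test <- function(edges, set_a, set_b, n_iter = 10000,
                               seed = 1L, count_shared_pairs = TRUE) {
  phys <- filter_physical(edges)
  nodes <- unique(c(phys$SYMBOL_A, phys$SYMBOL_B))
  a <- intersect(unique(set_a), nodes)
  b <- intersect(unique(set_b), nodes)
  sh <- intersect(a, b)
  s0 <- count_between(phys, a, b, count_shared_pairs)
  null <- bootstrap_null(phys, length(a), length(b), length(sh),
                         n_iter = n_iter, seed = seed, universe = nodes,
                         count_shared_pairs = count_shared_pairs)
  ep <- empirical_p(as.numeric(s0), null)
  c(ep, list(n_a = length(a), n_b = length(b), n_shared = length(sh),
             dropped_a = length(unique(set_a)) - length(a),
             dropped_b = length(unique(set_b)) - length(b),
             edges = attr(s0, "edges"), seed = seed))
}

#' Fold and hypergeometric enrichment of a gene set in an annotation
#'
#' `fold = (k/n) / (K/N_bg)` with k in-set hits among n target genes, K
#' the annotation size and N_bg the background; one-sided hypergeometric
#' upper-tail p for X >= k, plus the Fisher exact p on the 2x2 table. The
#' background size is an explicit required argument.
#'
#' @param k In-set hits; alternatively a character vector of target
#'   genes, in which case `n` must be the annotation's character vector
#'   and the third argument is the background size.
#' @param n Target-set size (or annotation members in character mode).
#' @param K Annotation size (or background size in character mode).
#' @param n_bg Background size.
#' @return List `k, n, K, n_bg, fold, p_hyper, p_fisher`.
#' @export
set_fold_enrichment <- function(k, n, K, n_bg) {
  if (is.character(k)) {
    targets <- k
    annotation <- n
    stopifnot(is.character(annotation), missing(n_bg))
    n_bg <- K
    k <- length(intersect(targets, annotation))
    n <- length(unique(targets))
    K <- length(unique(annotation))
  }
  if (any(c(n, K, n_bg) <= 0)) stop_cfg("n, K and n_bg must be positive")
  if (K > n_bg) stop_cfg("background (%d) smaller than annotation (%d)",
                         n_bg, K)
  if (k > min(n, K)) stop_cfg("k cannot exceed min(n, K)")
  fold <- (k / n) / (K / n_bg)
  p_hyper <- phyper(k - 1, K, n_bg - K, n, lower.tail = FALSE)
  tab <- matrix(c(k, n - k, K - k, n_bg - K - (n - k)), 2, 2)
  p_fisher <- fisher.test(tab, alternative = "greater")$p.value
  list(k = k, n = n, K = K, n_bg = n_bg, fold = fold, p_hyper = p_hyper,
       p_fisher = p_fisher)
}
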