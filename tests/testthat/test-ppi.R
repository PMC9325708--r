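# Physical-edge filtering, between-set counts, constrained bootstrap and
# annotation fold enrichment.

.toy_edges <- function() {
  data.frame(
    SYMBOL_A = c("P1", "P1", "P2", "N1", "P3", "Q1", "Q2", "P1", "Z1", "Z2"),
    SYMBOL_B = c("N1", "P2", "N2", "N2", "Q1", "Q2", "N1", "Q9", "Z2", "Z3"),
    EVIDENCE_TYPE = c("direct interaction", "physical association",
                      "association", "colocalization",
                      "genetic interaction", "synthetic lethality",
                      "direct interaction", "association",
                      "physical association", "direct interaction"),
    stringsAsFactors = FALSE
  )
}

test_that("only the four physical evidence categories are retained", {
  e <- .toy_edges()
  f <- filter_physical(e)
  expect_true(all(f$EVIDENCE_TYPE %in%
                    c("physical association", "association",
                      "colocalization", "direct interaction")))
  expect_equal(nrow(f), 8)
  expect_equal(attr(f, "n_removed"), 2)   # the two non-physical labels
  e$EVIDENCE_TYPE[1] <- "mystery"
  expect_warning(f2 <- filter_physical(e), "unknown")
  expect_equal(nrow(f2), 7)
})

test_that("count_between counts exactly the A-B edges once", {
  edges <- data.frame(SYMBOL_A = c("P1", "P1"), SYMBOL_B = c("N1", "P2"),
                      EVIDENCE_TYPE = "association")
  expect_equal(as.numeric(count_between(edges, c("P1", "P2"), "N1")), 1)
  expect_equal(as.numeric(count_between(edges[0, ], c("P1"), c("N1"))), 0)
  expect_error(count_between(edges, character(), "N1"), "nonempty")
  # shared members sit on either side; both-shared edges obey the switch
  ed2 <- data.frame(SYMBOL_A = c("S1", "S1", "A1"),
                    SYMBOL_B = c("S2", "A1", "B1"),
                    EVIDENCE_TYPE = "association")
  A <- c("A1", "S1", "S2"); B <- c("B1", "S1", "S2")
  expect_equal(as.numeric(count_between(ed2, A, B)), 3)
  expect_equal(as.numeric(count_between(ed2, A, B,
                                        count_shared_pairs = FALSE)), 2)
})

test_that("count_between equals the brute-force double loop", {
  set.seed(12)
  for (rep in 1:5) {
    nodes <- paste0("n", 1:50)
    edges <- data.frame(
      SYMBOL_A = sample(nodes, 200, TRUE),
      SYMBOL_B = sample(nodes, 200, TRUE),
      EVIDENCE_TYPE = "association", stringsAsFactors = FALSE)
    edges <- edges[edges$SYMBOL_A != edges$SYMBOL_B, ]
    A <- sample(nodes, 15); B <- sample(nodes, 10)
    expect_equal(as.numeric(count_between(edges, A, B)),
                 brute_count_between(edges, A, B))
    expect_equal(as.numeric(count_between(edges, A, B, FALSE)),
                 brute_count_between(edges, A, B, FALSE))
    # label swap leaves the count unchanged
    expect_equal(as.numeric(count_between(edges, B, A)),
                 as.numeric(count_between(edges, A, B)))
  }
})

test_that("bootstrap_null draws the constrained sets deterministically", {
  set.seed(77)
  nodes <- paste0("n", seq_len(434))
  edges <- data.frame(SYMBOL_A = sample(nodes, 800, TRUE),
                      SYMBOL_B = sample(nodes, 800, TRUE),
                      EVIDENCE_TYPE = "association")
  edges <- edges[edges$SYMBOL_A != edges$SYMBOL_B, ]
  # 404 + 43 - 13 = 434 distinct nodes are drawn per iteration: a
  # universe of exactly 434 works, one of 433 cannot
  n1 <- bootstrap_null(edges, 404, 43, 13, n_iter = 3, seed = 5,
                       universe = nodes)
  expect_length(n1, 3)
  expect_identical(n1, bootstrap_null(edges, 404, 43, 13, n_iter = 3,
                                      seed = 5, universe = nodes))
  expect_error(bootstrap_null(edges, 404, 43, 13, universe = nodes[1:433]),
               "too small")
  expect_error(bootstrap_null(edges, 10, 5, 6, universe = nodes),
               "n_shared")
  expect_length(bootstrap_null(edges, 10, 5, 2, n_iter = 1, seed = 1,
                               universe = nodes), 1)
})

test_that("the null count matches the closed-form Erdos-Renyi expectation", {
  # G(u, q): E[count] = q * (# cross pairs) with the constrained overlap
  set.seed(13)
  u <- 300; q <- 0.03
  pairs <- t(combn(u, 2))
  keep <- runif(nrow(pairs)) < q
  nodes <- paste0("n", 1:u)
  edges <- data.frame(SYMBOL_A = nodes[pairs[keep, 1]],
                      SYMBOL_B = nodes[pairs[keep, 2]],
                      EVIDENCE_TYPE = "association")
  dens <- nrow(edges) / nrow(pairs)
  nA <- 40; nB <- 12; nS <- 4
  nulls <- bootstrap_null(edges, nA, nB, nS, n_iter = 2000, seed = 3,
                          universe = nodes)
  exp_pairs <- (nA - nS) * (nB - nS) + nS * (nA - nS) + nS * (nB - nS) +
    choose(nS, 2)
  expect_lt(abs(mean(nulls) - dens * exp_pairs) / (dens * exp_pairs), 0.1)
})

test_that("empirical_p implements the printed formula exactly", {
  null <- rep(0, 10000)
  r <- empirical_p(5, null)
  expect_equal(r$p, 1 / 10001)            # no null count reaches s0
  null2 <- c(rep(10, 29), rep(0, 9971))
  expect_equal(empirical_p(10, null2)$p, 30 / 10001)  # ties in the tail
  expect_equal(empirical_p(10, null2)$p, 0.0030, tolerance = 1e-3)
  expect_equal(empirical_p(0, null)$p, 1)  # s0 <= every null count
  expect_equal(r$fold, Inf)
  expect_true(r$fold_infinite)
  expect_equal(empirical_p(10, c(4, 6))$fold, 2)
  # p monotone non-increasing in s0; minimum attainable p = 1/(N+1)
  set.seed(2)
  null3 <- rpois(500, 20)
  ps <- vapply(0:60, function(s) empirical_p(s, null3)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_gte(min(ps), 1 / 501)
})

test_that("bootstrap p detects the planted excess and stays flat on null
           networks", {
  # paper-scale constrained sets (404/43-like with 13 shared) on a
  # planted-fold-2.5 network
  universe <- sprintf("P%04d", 1:1500)
  lay <- small_study()$genome$layout
  cfg <- sim_config(seed = 19, ppi_q = 0.01)
  tr <- plant_truth(lay, "T1", matrix(1, 1, 1, dimnames = list("T1", "T1")),
                    ppi_fold = 2.5, ppi_set_a = universe[1:400],
                    ppi_set_b = c(universe[1:13], universe[401:427]))
  net <- simulate_ppi(tr, cfg, universe)
  res <- ppi_bootstrap_test(net, tr$ppi_set_a, tr$ppi_set_b,
                            n_iter = 400, seed = 11)
  expect_lt(res$p, 0.05)          # planted fold 2.5
  expect_gt(res$fold, 1.5)
  expect_identical(
    res$p, ppi_bootstrap_test(net, tr$ppi_set_a, tr$ppi_set_b,
                              n_iter = 400, seed = 11)$p)
  # swapping the sets leaves s0, p and fold unchanged
  swap <- ppi_bootstrap_test(net, tr$ppi_set_b, tr$ppi_set_a,
                             n_iter = 400, seed = 11)
  expect_equal(swap$s0, res$s0)
  expect_equal(swap$fold, res$fold)
})

test_that("fold enrichment reproduces the worked annotation examples", {
  r <- set_fold_enrichment(5, 10, 100, 1000)
  expect_equal(r$fold, 5)
  expect_equal(r$p_hyper, phyper(4, 100, 900, 10, lower.tail = FALSE))
  sat <- set_fold_enrichment(10, 10, 1000, 1000)
  expect_equal(sat$fold, 1)
  expect_equal(sat$p_fisher, 1)
  expect_error(set_fold_enrichment(5, 10, 100, 50), "smaller than")
  expect_error(set_fold_enrichment(20, 10, 100, 1000), "exceed")
  # hypergeometric and Fisher agree (one-sided, same table)
  r2 <- set_fold_enrichment(102, 118, 7907, 20338)
  expect_equal(r2$p_hyper, r2$p_fisher, tolerance = 1e-10)
})
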