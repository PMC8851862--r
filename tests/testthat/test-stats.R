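# Fisher, BH-FDR, hypergeometric overlap, conserved-set validation, pair
# report, and the enrichment power property.

test_that("fisher_two_sided reproduces printed and derived examples", {
  expect_equal(signif(fisher_two_sided(20, 286, 7, 473)$p, 1), 2e-4)
  expect_lt(fisher_two_sided(5, 448, 20, 286)$p, 1e-4)
  expect_equal(fisher_two_sided(1, 9, 9, 1)$p, 202 / 184756)
  expect_equal(fisher_two_sided(5, 5, 5, 5)$p, 1)
  expect_equal(fisher_two_sided(0, 0, 3, 5)$p, 1)  # zero margin convention
  # agrees with stats::fisher.test on a handful of tables
  for (tb in list(c(3, 10, 8, 4), c(1, 0, 5, 9), c(12, 2, 3, 18))) {
    ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(fisher_two_sided(tb[1], tb[2], tb[3], tb[4])$p, ft$p.value,
                 tolerance = 1e-10)
  }
})

test_that("fisher p is invariant under simultaneous row and column swap", {
  set.seed(81)
  for (i in 1:25) {
    tb <- rpois(4, 6)
    p1 <- fisher_two_sided(tb[1], tb[2], tb[3], tb[4])$p
    p2 <- fisher_two_sided(tb[4], tb[3], tb[2], tb[1])$p
    expect_equal(p1, p2)
  }
})

test_that("BH adjustment matches hand-stepped values and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(91)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("hypergeometric overlap test: examples and enumeration", {
  ot <- overlap_hypergeometric(4, 5, 10, 3)
  expect_equal(ot$expected, 2)
  expect_equal(ot$p_hyper, 11 / 42)
  expect_equal(overlap_hypergeometric(4, 5, 10, 0)$p_hyper, 1)
  expect_error(overlap_hypergeometric(8, 5, 6, 2), "universe")
  expect_error(overlap_hypergeometric(4, 5, 10, 5), "exceeds")
  # paper-shaped instance: structural reference (N back-calculated from the
  # printed expectation 1.42 = 167 * 139 / N)
  N <- round(167 * 139 / 1.42)
  ot2 <- overlap_hypergeometric(167, 139, N, 20)
  expect_equal(ot2$expected, 1.42, tolerance = 1e-3)
  expect_lt(ot2$p_hyper, 1e-12)
})

test_that("hypergeometric matches Monte-Carlo resampling within 3 SE", {
  set.seed(101)
  for (i in 1:5) {
    N <- sample(15:30, 1); n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    obs <- sample(0:min(n1, n2), 1)
    draws <- replicate(1e4, length(intersect(sample.int(N, n1), sample.int(N, n2))))
    mc <- mean(draws >= obs)
    se <- sqrt(mc * (1 - mc) / 1e4)
    expect_lt(abs(overlap_hypergeometric(n1, n2, N, obs)$p_hyper - mc),
              3 * se + 1e-9)
  }
})

test_that("conserved-set validation reports the printed percentage", {
  cons <- sprintf("c%05d", 1:13650)
  calls <- c(cons[1:41], "x1", "x2")
  v <- conserved_set_validation(calls, cons)
  expect_equal(round(v$percent, 2), 0.30)  # printed to two decimals
  expect_equal(conserved_set_validation(character(0), cons)$percent, 0)
  expect_error(conserved_set_validation("a", character(0)), "non-empty")
})

test_that("pair overlap report builds the printed comparison table", {
  # two pairs with overlap/size 20/306 and 7/480 -> Fisher on (20,286,7,473)
  lists <- list(n = c(sprintf("s%03d", 1:20), sprintf("n%03d", 1:147)),
                b = c(sprintf("s%03d", 1:20), sprintf("b%03d", 1:119)),
                g = c(sprintf("t%03d", 1:7), sprintf("g%03d", 1:229)),
                r = c(sprintf("t%03d", 1:7), sprintf("r%03d", 1:237)))
  plan <- data.frame(species1 = c("n", "g"), species2 = c("b", "r"),
                     type = c("homotypic", "heterotypic"))
  rep <- pair_overlap_report(lists, plan)
  expect_equal(rep$pairs$overlap, c(20L, 7L))
  expect_equal(rep$pairs$size, c(306L, 480L))
  expect_equal(signif(rep$comparisons$p, 1), 2e-4)
  # identical and disjoint lists
  l2 <- list(a = c("x", "y"), b = c("x", "y"), c = c("z"))
  r2 <- pair_overlap_report(l2, data.frame(species1 = c("a", "a"),
                                           species2 = c("b", "c")))
  expect_equal(r2$pairs$overlap, c(2L, 0L))
})

test_that("enrichment recovers a planted group (power property)", {
  # world: 600 genes, group A holds 90; pseudogenes drawn so that membership
  # odds are ~5x background; 30 pseudogenes per replicate
  set.seed(111)
  genes <- sprintf("g%04d", 1:600)
  inA <- genes[1:90]
  membership <- rbind(data.frame(gene = inA, group = "A"),
                      data.frame(gene = genes[301:390], group = "B"))
  pA <- 0.15 * 5 / (0.85 + 0.15 * 5)  # odds-ratio-5 membership probability
  hits <- 0L
  for (rep in 1:10) {
    member <- runif(30) < pA
    ps <- c(sample(inA, sum(member)), sample(setdiff(genes, inA), sum(!member)))
    bg <- setdiff(genes, ps)
    res <- efg_test(membership, ps, bg, alpha = 0.05)
    if (res$efg[res$group == "A"] && !res$efg[res$group == "B"]) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.9)
})
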