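test_that("contingency counts partition the case set", {
  a1 <- c(rep(TRUE, 4), rep(FALSE, 6))
  a2 <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  cc <- build_contingency(a1, a2)
  expect_equal(cc$comutant, 3)
  expect_equal(cc$g1_only, 1)
  expect_equal(cc$g2_only, 1)
  expect_equal(cc$neither, 5)
  expect_equal(cc$total, 10)
  expect_equal(cc$co_frac, 0.3)
  # no gene1 alterations
  cc0 <- build_contingency(rep(FALSE, 5), c(TRUE, rep(FALSE, 4)))
  expect_equal(cc0$comutant, 0)
  expect_equal(cc0$g1_only, 0)
  # order invariance
  perm <- sample(10)
  expect_equal(unclass(build_contingency(a1[perm], a2[perm])), unclass(cc))
})

test_that("directional Fisher test matches hand-derived values", {
  # (3,1,1,5): upper tail = [C(4,3)C(6,1) + C(4,4)C(6,0)] / C(10,4)
  expect_equal(fisher_one_tailed(3, 4, 4, 10, "concurrent"), 25 / 210,
               tolerance = 1e-12)
  # P(X >= 0) = 1 whatever the margins
  expect_equal(fisher_one_tailed(0, 3, 4, 10, "concurrent"), 1)
  # degenerate margins carry p = 1 in both directions
  for (d in c("concurrent", "exclusive")) {
    expect_equal(fisher_one_tailed(0, 0, 4, 10, d), 1)
    expect_equal(fisher_one_tailed(4, 10, 4, 10, d), 1)
  }
})

test_that("Fisher tails agree with the combinatorial oracle on all small tables", {
  for (N in 1:9) {
    for (m1 in 0:N) for (m2 in 0:N) {
      lo <- max(0, m1 + m2 - N)
      hi <- min(m1, m2)
      for (a in lo:hi) {
        up <- fisher_one_tailed(a, m1, m2, N, "concurrent")
        lo_p <- fisher_one_tailed(a, m1, m2, N, "exclusive")
        degenerate <- m1 == 0 || m2 == 0 || m1 == N || m2 == N
        if (!degenerate) {
          expect_equal(up, hyper_tail_oracle(a, m1, m2, N, "concurrent"),
                       tolerance = 1e-12)
          expect_equal(lo_p, hyper_tail_oracle(a, m1, m2, N, "exclusive"),
                       tolerance = 1e-12)
          # tail identity: both tails overlap exactly at X = a
          pmf <- stats::dhyper(a, m1, N - m1, m2)
          expect_equal(up + lo_p, 1 + pmf, tolerance = 1e-12)
        } else {
          expect_equal(up, 1)
          expect_equal(lo_p, 1)
        }
      }
    }
  }
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_adjust(0.03, family_size = 1), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:100, 1)
    p <- stats::runif(n)^sample(1:3, 1)
    fam <- n + sample(0:20, 1)
    adj <- bh_adjust(p, family_size = fam)
    expect_equal(adj, bh_oracle(p, fam), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("independence expectation is the product of marginal fractions", {
  expect_equal(independence_expectation(0.5, 0.5), 0.25)
  expect_equal(independence_expectation(0, 0.7), 0)
  cc <- build_contingency(c(rep(TRUE, 4), rep(FALSE, 6)),
                          c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5)))
  expect_equal(independence_expectation(cc), 0.16)
  expect_equal(cc$co_frac, 0.30)
})

test_that("screen output is invariant to case order and pair orientation", {
  reg <- make_manual_registry(
    list(S1 = c("A", "B"), S2 = "A", S3 = "B", S4 = character(),
         S5 = c("A", "B"), S6 = "A", S7 = character(), S8 = "B"),
    cancer_types = rep(c("t1", "t2"), 4))
  scr <- run_screen(reg, c("A", "B"))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  reg2 <- reg
  reg2$cases <- reg$cases[perm]
  scr2 <- run_screen(reg2, c("B", "A"))
  expect_equal(scr2$full_results, scr$full_results)
  expect_equal(scr2$pair_summary, scr$pair_summary)
})

test_that("screen emits the published header vocabulary and flags", {
  reg <- make_manual_registry(
    list(S1 = c("A", "B"), S2 = "A", S3 = "B", S4 = character()))
  scr <- run_screen(reg, c("A", "B"))
  expect_named(scr$full_results, c(
    "gene1", "gene2", "cancer_type", "comutant", "g1_mutant", "g2_mutant",
    "total", "co.frac", "g1.frac", "g2.frac", "expected.co.frac",
    "concurrent.pv", "concurrent.padj", "exclusive.pv", "exclusive.padj",
    "concurrent.pv.sig", "concurrent.padj.sig", "exclusive.pv.sig",
    "exclusive.padj.sig", "tested"))
  fr <- scr$full_results
  expect_equal(fr$comutant, 1L)
  expect_equal(fr$g1_mutant, 2L)
  expect_equal(fr$g2_mutant, 2L)
  expect_equal(fr$total, 4L)
  expect_true(all(fr$concurrent.padj >= fr$concurrent.pv - 1e-15))
  expect_true(all(c("overall.comut.frac", "concurrent.padj.sig") %in%
                    names(scr$pair_summary)))
  expect_true(all(c("n.sig.pairs", "avg.total") %in%
                    names(scr$cancer_type_summary)))
})

test_that("zero-covered pairs appear as untested rows, not errors", {
  reg <- make_manual_registry(list(S1 = "A", S2 = "B"), genes = c("A", "B"))
  # add a gene C known to the gene list but absent from every panel
  scr <- run_screen(reg, c("A", "B", "C"))
  un <- scr$full_results[is.na(cancer_type)]
  expect_equal(nrow(un), 2L)   # (A,C) and (B,C)
  expect_true(all(!un$tested))
  ps <- scr$pair_summary
  expect_equal(nrow(ps), 3L)
  expect_equal(ps[gene2 == "C", n.types.tested], c(0L, 0L))
})

test_that("min_cases strata stay in the BH family but get no p-value", {
  reg <- make_manual_registry(
    list(S1 = c("A", "B"), S2 = "A", S3 = "B", S4 = character(),
         S5 = c("A", "B"), S6 = "A", S7 = "B", S8 = character(),
         S9 = c("A", "B")),
    cancer_types = c(rep("big", 8), "tiny"))
  scr <- run_screen(reg, c("A", "B"), min_cases = 5)
  fr <- scr$full_results
  expect_true(is.na(fr[cancer_type == "tiny", concurrent.pv]))
  expect_false(fr[cancer_type == "tiny", tested])
  # family of 2 strata: the tested p is doubled by step-up
  p_big <- fr[cancer_type == "big", concurrent.pv]
  expect_equal(fr[cancer_type == "big", concurrent.padj],
               min(1, 2 * p_big))
})

test_that("diversity ranking orders by significant types then comutant load", {
  ps <- data.table::data.table(
    gene1 = c("A", "C", "A"), gene2 = c("B", "D", "C"),
    overall.comut.frac = c(0.1, 0.2, 0.3),
    total.comutant = c(10L, 50L, 50L), n.types.tested = 5L,
    concurrent.pv.sig = c(5L, 2L, 2L),
    concurrent.padj.sig = c(5L, 2L, 2L),
    exclusive.pv.sig = 0L, exclusive.padj.sig = 0L)
  rk <- diversity_ranking(ps)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk[1, .(gene1, gene2)], data.table::data.table(gene1 = "A",
                                                              gene2 = "B"))
  # tie at 2 significant types broken by comutant count tie -> lexicographic
  expect_equal(rk[2:3, gene1], c("A", "C"))
})

test_that("ranking is invariant under cancer-type relabeling", {
  reg <- make_manual_registry(
    list(S1 = c("A", "B"), S2 = c("A", "B"), S3 = "A", S4 = "B",
         S5 = character(), S6 = c("A", "B")),
    cancer_types = rep(c("x", "y"), 3))
  r1 <- diversity_ranking(run_screen(reg, c("A", "B")))
  reg$cases$cancer_type_detailed <-
    c(x = "y", y = "x")[reg$cases$cancer_type_detailed]
  r2 <- diversity_ranking(run_screen(reg, c("A", "B")))
  expect_equal(r1[, !"overall.comut.frac"], r2[, !"overall.comut.frac"])
  expect_equal(r1$overall.comut.frac, r2$overall.comut.frac)
})
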