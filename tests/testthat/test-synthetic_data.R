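test_that("simulation is bit-for-bit reproducible per seed", {
  cfg <- registry_sim_config(n_cancer_types = 4, cases_per_type = 50,
                             seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_registry(cfg, dir = d1)
  simulate_registry(cfg, dir = d2)
  for (f in c("clinical.tsv", "mutations.tsv", "panels.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # different seed -> different draws
  d3 <- simulate_registry(registry_sim_config(n_cancer_types = 4,
                                              cases_per_type = 50,
                                              seed = 100))
  expect_false(identical(d3$registry$mutations,
                         simulate_registry(cfg)$registry$mutations))
})

test_that("generated bundles re-read with zero dropped rows", {
  cfg <- registry_sim_config(n_cancer_types = 4, cases_per_type = 80,
                             del_given_loss = 0.3, fus_given_loss = 0.1,
                             amp_rate = 0.02, seed = 7)
  sim <- simulate_registry(cfg, dir = tempfile())
  reg <- read_registry(sim$paths["clinical"], sim$paths["mutations"],
                       sim$paths["panels"], cna_path = sim$paths["cna"],
                       fusion_path = sim$paths["fusions"])
  expect_equal(sum(reg$dropped), 0L)
  expect_equal(nrow(reg$cases), 320L)
  expect_true(all(reg$cna$value %in% c(-2L, -1L, 1L, 2L)))
})

test_that("zero baseline rate yields no mutation rows", {
  sim <- simulate_registry(registry_sim_config(
    n_cancer_types = 2, cases_per_type = 30, baseline_rate = 0, seed = 1))
  expect_equal(nrow(sim$registry$mutations), 0L)
})

test_that("per-gene mutation frequencies track the configured rates", {
  rates <- stats::setNames(seq(0.05, 0.5, length.out = 30),
                           default_sim_genes())
  cfg <- registry_sim_config(cases_per_type = 300, baseline_rate = rates,
                             seed = 12)
  sim <- simulate_registry(cfg)
  reg <- sim$registry
  covered_n <- sapply(default_sim_genes(), function(g) {
    assays <- names(cfg$panels)[sapply(cfg$panels, function(p) g %in% p)]
    sum(reg$cases$assay_id %in% assays)
  })
  hits <- table(factor(reg$mutations$gene, levels = default_sim_genes()))
  for (g in default_sim_genes()) {
    p <- rates[[g]]
    se <- sqrt(p * (1 - p) / covered_n[[g]])
    expect_lt(abs(hits[[g]] / covered_n[[g]] - p), 3 * se + 1e-9)
  }
})

test_that("unprofiled genes never emit evidence rows", {
  cfg <- registry_sim_config(n_cancer_types = 2, cases_per_type = 100,
                             del_given_loss = 0.5, seed = 31)
  sim <- simulate_registry(cfg)
  reg <- sim$registry
  on_panel <- function(dt) mapply(function(g, s) {
    g %in% cfg$panels[[reg$cases[sample_id == s, assay_id]]]
  }, dt$gene, dt$sample_id)
  expect_true(all(on_panel(reg$mutations)))
  if (nrow(reg$cna)) expect_true(all(on_panel(reg$cna)))
})

test_that("an OR = 1 spec leaves the empirical odds ratio near one", {
  enr <- data.frame(gene1 = "RB1", gene2 = "TP53",
                    cancer_type = "cancer_type_01", or = 1)
  cfg <- registry_sim_config(n_cancer_types = 1, cases_per_type = 10000,
                             baseline_rate = 0.3, enrichment = enr,
                             seed = 77)
  sim <- simulate_registry(cfg)
  gt <- sim$ground_truth
  tab <- table(gt$genotype %in% c("comut", "g1_only"),
               gt$genotype %in% c("comut", "g2_only"))
  or_hat <- tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1])
  expect_gt(or_hat, 0.85)
  expect_lt(or_hat, 1.18)
})

test_that("odds-ratio tilting hits the target OR with preserved marginals", {
  enr <- data.frame(gene1 = "RB1", gene2 = "TP53",
                    cancer_type = "cancer_type_01", or = 8)
  cfg <- registry_sim_config(n_cancer_types = 1, cases_per_type = 20000,
                             baseline_rate = 0.2, enrichment = enr,
                             seed = 13)
  sim <- simulate_registry(cfg)
  gt <- sim$ground_truth
  g1 <- gt$genotype %in% c("comut", "g1_only")
  g2 <- gt$genotype %in% c("comut", "g2_only")
  tab <- table(g1, g2)
  or_hat <- tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1])
  expect_gt(or_hat, 6)
  expect_lt(or_hat, 10.5)
  expect_lt(abs(mean(g2) - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
})

test_that("enrichment referencing an uncovered gene is a config error", {
  panels <- panel_registry(list(P1 = c("RB1", "TP53")))
  expect_error(registry_sim_config(
    genes = c("RB1", "TP53", "KRAS"), panels = panels,
    enrichment = data.frame(gene1 = "RB1", gene2 = "KRAS",
                            cancer_type = "cancer_type_01", or = 5),
    seed = 1), "KRAS")
})

test_that("cell-line simulator: zero noise limit recovers effects exactly", {
  effects <- data.table::data.table(feature = "RPPA_f0001",
                                    comparison = "comut_vs_wt",
                                    effect = 2)
  cfg <- cellline_sim_config(noise_sd = 1e-10, lineage_sd = 1,
                             effects = effects, seed = 5)
  sim <- simulate_cellline_panel(cfg)
  m <- sim$matrices$RPPA
  sub <- sim$panel[genotype %in% c("comut", "wt")]
  fit <- fit_feature_model(m[sub$cell_line_id, "RPPA_f0001"], sub$lineage,
                           sub$genotype == "comut")
  expect_equal(fit$coefficient, 2, tolerance = 1e-8)
  sim2 <- simulate_cellline_panel(cfg)
  expect_identical(sim2$ground_truth, effects)
})

test_that("cell-line simulation is seed-reproducible", {
  cfg <- cellline_sim_config(n_features = 20, seed = 8)
  s1 <- simulate_cellline_panel(cfg)
  s2 <- simulate_cellline_panel(cfg)
  expect_identical(s1$matrices, s2$matrices)
  expect_identical(s1$panel, s2$panel)
})
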