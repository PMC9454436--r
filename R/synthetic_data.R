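# Seeded generators of registry-style and cell-line fixture data with
# known ground truth. A latent per-(gene, case) "loss" status is drawn
# first (with odds-ratio tilting for configured pair enrichments); the
# observable evidence layers (mutation rows, discrete copy-number calls,
# fusion rows) are emitted conditionally on that latent status, and only
# for genes on the case's panel.

#' Default gene universe of the mini registry simulator
#' @return Character vector of 30 cancer-gene symbols.
#' @export
default_sim_genes <- function() {
  c("AKT1", "ALK", "APC", "ARID1A", "ATM", "BRAF", "BRCA1", "BRCA2",
    "CDH1", "CDKN2A", "CTNNB1", "EGFR", "ERBB2", "FBXW7", "GNAS", "IDH1",
    "KIT", "KRAS", "MET", "MYC", "NF1", "NOTCH1", "NRAS", "PIK3CA",
    "PTEN", "RB1", "SMAD4", "STK11", "TP53", "VHL")
}

#' Default heterogeneous panel set over a gene universe
#'
#' Five assays covering different subsets so per-pair denominators vary:
#' one full panel, and four partial panels. The first and last two genes
#' of the (sorted) universe — which include RB1 and TP53 in the default
#' universe — are on every panel.
#'
#' @param genes Gene universe.
#' @return A [panel_registry] of 5 assays.
#' @export
default_sim_panels <- function(genes = default_sim_genes()) {
  g <- sort(unique(toupper(genes)))
  n <- length(g)
  stopifnot(n >= 10)
  core <- c("RB1", "TP53")
  if (!all(core %in% g)) core <- g[c(1L, n)]
  sub <- function(idx) unique(c(core, g[idx]))
  panel_registry(list(
    ASSAY_FULL = g,
    ASSAY_A = sub(seq_len(ceiling(0.8 * n))),
    ASSAY_B = sub(seq(floor(0.25 * n), n)),
    ASSAY_C = sub(c(seq_len(floor(0.4 * n)), seq(ceiling(0.75 * n), n))),
    ASSAY_D = sub(seq(floor(0.3 * n), ceiling(0.7 * n)))
  ))
}

#' Configuration for the registry simulator
#'
#' @param n_cancer_types Number of detailed cancer types.
#' @param cases_per_type Cases per cancer type (scalar or vector of
#'   length `n_cancer_types`).
#' @param genes Gene universe.
#' @param panels A [panel_registry] over `genes`.
#' @param panel_weights Sampling weights per assay (default uniform).
#' @param baseline_rate Per-gene latent loss probability; scalar or
#'   named vector over `genes`.
#' @param enrichment Optional data.frame `gene1`, `gene2`,
#'   `cancer_type`, `or`: pairwise odds ratio of joint loss injected in
#'   the named stratum, marginals preserved.
#' @param mut_given_loss P(mutation row | latent loss) (default 1).
#' @param del_given_loss P(copy-number loss call | latent loss)
#'   (default 0; calls are -1 or -2, and a CNA matrix is emitted for the
#'   genes on each case's panel whenever this or `amp_rate` is positive).
#' @param fus_given_loss P(fusion row | latent loss) (default 0).
#' @param amp_rate Background P(copy-number gain call) independent of
#'   loss (default 0).
#' @param coupling_pair Gene pair whose joint latent genotype drives the
#'   clinical couplings (default RB1/TP53).
#' @param death_rate Baseline P(dead) (default 0.3); `vital_coupling`
#'   optionally overrides per genotype, a named vector over
#'   `comut`, `g1_only`, `g2_only`, `wt`.
#' @param metastasis_rate Baseline P(metastatic sample) (default 0.4);
#'   `metastasis_coupling` analogous to `vital_coupling`.
#' @param vital_unknown_rate,sample_type_unknown_rate Fractions blanked
#'   to unknown (default 0.05 each).
#' @param vital_coupling,metastasis_coupling See above; default NULL
#'   (no coupling).
#' @param cancer_type_names Optional explicit stratum names.
#' @param seed Mandatory integer seed.
#' @return List of class `registry_sim_config`.
#' @export
registry_sim_config <- function(n_cancer_types = 20, cases_per_type = 400,
                                genes = default_sim_genes(),
                                panels = default_sim_panels(genes),
                                panel_weights = NULL,
                                baseline_rate = 0.3,
                                enrichment = NULL,
                                mut_given_loss = 1, del_given_loss = 0,
                                fus_given_loss = 0, amp_rate = 0,
                                coupling_pair = NULL,
                                death_rate = 0.3, vital_coupling = NULL,
                                metastasis_rate = 0.4,
                                metastasis_coupling = NULL,
                                vital_unknown_rate = 0.05,
                                sample_type_unknown_rate = 0.05,
                                cancer_type_names = NULL,
                                seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  genes <- sort(unique(toupper(genes)))
  if (!inherits(panels, "panel_registry")) panels <- panel_registry(panels)
  stopifnot(all(unlist(panels) %in% genes))
  if (is.null(panel_weights)) panel_weights <- rep(1, length(panels))
  stopifnot(length(panel_weights) == length(panels), all(panel_weights > 0))
  if (length(baseline_rate) == 1L)
    baseline_rate <- stats::setNames(rep(baseline_rate, length(genes)), genes)
  stopifnot(all(genes %in% names(baseline_rate)),
            all(baseline_rate >= 0 & baseline_rate <= 1))
  probs <- c(mut_given_loss, del_given_loss, fus_given_loss, amp_rate,
             death_rate, metastasis_rate, vital_unknown_rate,
             sample_type_unknown_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  if (!is.null(enrichment)) {
    enrichment <- data.table::as.data.table(enrichment)
    stopifnot(all(c("gene1", "gene2", "cancer_type", "or") %in%
                    names(enrichment)),
              all(enrichment$or > 0))
    enrichment[, `:=`(gene1 = toupper(gene1), gene2 = toupper(gene2))]
    pg <- unique(c(enrichment$gene1, enrichment$gene2))
    uncov <- pg[!vapply(pg, function(g)
      any(vapply(panels, function(p) g %in% p, logical(1))), logical(1))]
    if (length(uncov))
      stop("enrichment references gene(s) absent from all panels: ",
           paste(uncov, collapse = ", "))
  }
  if (is.null(coupling_pair))
    coupling_pair <- if (all(c("RB1", "TP53") %in% genes))
      c("RB1", "TP53") else genes[1:2]
  coupling_pair <- toupper(coupling_pair)
  stopifnot(length(coupling_pair) == 2L, all(coupling_pair %in% genes))
  if (is.null(cancer_type_names))
    cancer_type_names <- sprintf("cancer_type_%02d", seq_len(n_cancer_types))
  stopifnot(length(cancer_type_names) == n_cancer_types)
  cases_per_type <- rep_len(cases_per_type, n_cancer_types)
  structure(list(
    n_cancer_types = n_cancer_types, cases_per_type = cases_per_type,
    genes = genes, panels = panels, panel_weights = panel_weights,
    baseline_rate = baseline_rate[genes], enrichment = enrichment,
    mut_given_loss = mut_given_loss, del_given_loss = del_given_loss,
    fus_given_loss = fus_given_loss, amp_rate = amp_rate,
    coupling_pair = coupling_pair, death_rate = death_rate,
    vital_coupling = vital_coupling, metastasis_rate = metastasis_rate,
    metastasis_coupling = metastasis_coupling,
    vital_unknown_rate = vital_unknown_rate,
    sample_type_unknown_rate = sample_type_unknown_rate,
    cancer_type_names = cancer_type_names, seed = as.integer(seed)),
    class = "registry_sim_config")
}

# Joint loss probability p11 with marginals (p1, p2) and odds ratio or:
# the root of (or-1) x^2 - [(or-1)(p1+p2) + 1] x + or p1 p2 = 0 inside
# the Frechet bounds.
joint_prob_from_or <- function(p1, p2, or) {
  if (abs(or - 1) < 1e-12) return(p1 * p2)
  a <- or - 1
  b <- -((or - 1) * (p1 + p2) + 1)
  cc <- or * p1 * p2
  disc <- sqrt(b^2 - 4 * a * cc)
  roots <- c((-b - disc) / (2 * a), (-b + disc) / (2 * a))
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  ok <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
  if (length(ok) == 0L) stop("no admissible joint probability for OR = ", or)
  min(max(ok[1], lo), hi)
}

#' Simulate a registry bundle with known ground truth
#'
#' Draws the latent loss matrix gene-by-gene (independent Bernoulli at
#' the configured baseline rates; for each configured enrichment, the
#' second gene is redrawn in that stratum from the odds-ratio-tilted
#' conditional so the marginals are preserved exactly), then emits
#' mutation / copy-number / fusion evidence conditionally on loss, and
#' clinical labels coupled to the latent genotype of the coupling pair.
#' Bit-for-bit reproducible per seed.
#'
#' @param config A [registry_sim_config()].
#' @param dir Optional output directory; when given, the registry file
#'   dialects plus `ground_truth.tsv` are written there.
#' @return List of class `comut_sim`: `registry` (a `comut_registry`),
#'   `ground_truth` (per-case latent loss of the coupling pair plus the
#'   enrichment spec), and `paths` when `dir` was given.
#' @export
simulate_registry <- function(config, dir = NULL) {
  stopifnot(inherits(config, "registry_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n_cases <- sum(config$cases_per_type)
  cases <- data.table(
    sample_id = sprintf("S%06d", seq_len(n_cases)),
    patient_id = sprintf("P%06d", seq_len(n_cases)),
    cancer_type_detailed = rep(config$cancer_type_names,
                               config$cases_per_type),
    assay_id = sample(names(config$panels), n_cases, replace = TRUE,
                      prob = config$panel_weights))

  genes <- config$genes
  loss <- matrix(FALSE, length(genes), n_cases,
                 dimnames = list(genes, cases$sample_id))
  for (g in genes)
    loss[g, ] <- stats::runif(n_cases) < config$baseline_rate[[g]]
  if (!is.null(config$enrichment)) {
    for (k in seq_len(nrow(config$enrichment))) {
      e <- config$enrichment[k]
      idx <- which(cases$cancer_type_detailed == e$cancer_type)
      if (length(idx) == 0L) next
      p1 <- config$baseline_rate[[e$gene1]]
      p2 <- config$baseline_rate[[e$gene2]]
      p11 <- joint_prob_from_or(p1, p2, e$or)
      g1 <- loss[e$gene1, idx]
      cond <- ifelse(g1, p11 / p1, (p2 - p11) / (1 - p1))
      loss[e$gene2, idx] <- stats::runif(length(idx)) < cond
    }
  }

  covered <- matrix(FALSE, length(genes), n_cases,
                    dimnames = dimnames(loss))
  for (a in names(config$panels))
    covered[config$panels[[a]], cases$assay_id == a] <- TRUE

  emit <- function(prob_mat) {
    hit <- which(prob_mat & covered, arr.ind = TRUE)
    data.table(gene = genes[hit[, 1]], sample_id = cases$sample_id[hit[, 2]])
  }
  vclasses <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
                "Splice_Site")
  mut <- emit(loss & matrix(stats::runif(length(loss)) <
                              config$mut_given_loss, nrow(loss)))
  mut[, variant_class := sample(vclasses, .N, replace = TRUE)]

  cna <- data.table(gene = character(), sample_id = character(),
                    value = integer())
  if (config$del_given_loss > 0 || config$amp_rate > 0) {
    del <- emit(loss & matrix(stats::runif(length(loss)) <
                                config$del_given_loss, nrow(loss)))
    del[, value := sample(c(-2L, -1L), .N, replace = TRUE)]
    amp <- emit(matrix(stats::runif(length(loss)) < config$amp_rate,
                       nrow(loss)))
    amp[, value := sample(c(1L, 2L), .N, replace = TRUE)]
    cna <- data.table::rbindlist(list(del, amp), use.names = TRUE)
    cna <- cna[!duplicated(cna, by = c("gene", "sample_id"))]
  }
  fus <- emit(loss & matrix(stats::runif(length(loss)) <
                              config$fus_given_loss, nrow(loss)))

  cp <- config$coupling_pair
  geno <- data.table::fifelse(
    loss[cp[1], ] & loss[cp[2], ], "comut",
    data.table::fifelse(loss[cp[1], ], "g1_only",
                        data.table::fifelse(loss[cp[2], ], "g2_only", "wt")))
  rate_for <- function(coupling, base)
    if (is.null(coupling)) rep(base, n_cases) else {
      stopifnot(all(c("comut", "g1_only", "g2_only", "wt") %in%
                      names(coupling)))
      unname(coupling[geno])
    }
  dead <- stats::runif(n_cases) < rate_for(config$vital_coupling,
                                           config$death_rate)
  vital <- ifelse(dead, "dead", "alive")
  vital[stats::runif(n_cases) < config$vital_unknown_rate] <- "unknown"
  met <- stats::runif(n_cases) < rate_for(config$metastasis_coupling,
                                          config$metastasis_rate)
  stype <- ifelse(met, "metastasis", "primary")
  stype[stats::runif(n_cases) < config$sample_type_unknown_rate] <- "unknown"
  cases[, `:=`(vital_status = vital, sample_type = stype)]
  data.table::setcolorder(cases, c("sample_id", "patient_id",
                                   "cancer_type_detailed", "vital_status",
                                   "sample_type", "assay_id"))

  registry <- structure(list(panels = config$panels, cases = cases,
                             mutations = mut, cna = cna, fusions = fus,
                             dropped = c(mutations = 0L, cna = 0L,
                                         fusions = 0L)),
                        class = "comut_registry")
  ground_truth <- data.table(sample_id = cases$sample_id,
                             cancer_type = cases$cancer_type_detailed,
                             genotype = geno)
  out <- list(registry = registry, ground_truth = ground_truth,
              config = config)
  if (!is.null(dir)) {
    paths <- write_registry(registry, dir)
    gt_path <- file.path(dir, "ground_truth.tsv")
    data.table::fwrite(ground_truth, gt_path, sep = "\t")
    out$paths <- c(paths, ground_truth = gt_path)
  }
  structure(out, class = "comut_sim")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Configuration for the cell-line panel simulator
#'
#' @param n_lines Number of cell lines (default 60).
#' @param lineages Lineage names (default 4 tissue labels).
#' @param lineage_props Sampling proportions (default uniform).
#' @param genotype_props Named proportions over `comut`, `rb1_only`,
#'   `tp53_only`, `wt`; must sum to 1. Default mirrors a pan-cancer line
#'   panel: few RB1-only lines. Proportions (like `lineage_props`) are
#'   realized as exact per-class counts in randomized order — the panel
#'   composition is a fixed property of the dataset being emulated, not
#'   a sampling outcome.
#' @param n_features Features per source (default 200).
#' @param sources Data source names (default `"RPPA"`).
#' @param effects Optional data.frame `feature`, `comparison`
#'   (`"comut_vs_wt"` or `"tp53only_vs_wt"`), `effect`: additive shift
#'   applied to the mutant class of that comparison, in feature units —
#'   equal to sigma units at the default unit `noise_sd`.
#' @param noise_sd Residual Gaussian sd (default 1).
#' @param lineage_sd Sd of per-(lineage, feature) baseline shifts
#'   (default 1).
#' @param missing_rate Fraction of entries blanked to NA (default 0).
#' @param seed Mandatory integer seed.
#' @return List of class `cellline_sim_config`.
#' @export
cellline_sim_config <- function(n_lines = 60,
                                lineages = c("lung", "breast", "skin",
                                             "colon"),
                                lineage_props = NULL,
                                genotype_props = c(comut = 0.25,
                                                   rb1_only = 0.05,
                                                   tp53_only = 0.35,
                                                   wt = 0.35),
                                n_features = 200, sources = "RPPA",
                                effects = NULL, noise_sd = 1,
                                lineage_sd = 1, missing_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(lineage_props))
    lineage_props <- rep(1 / length(lineages), length(lineages))
  stopifnot(length(lineage_props) == length(lineages),
            abs(sum(genotype_props) - 1) < 1e-8,
            all(c("comut", "rb1_only", "tp53_only", "wt") %in%
                  names(genotype_props)),
            noise_sd > 0, missing_rate >= 0, missing_rate < 1)
  if (!is.null(effects)) {
    effects <- data.table::as.data.table(effects)
    stopifnot(all(c("feature", "comparison", "effect") %in% names(effects)),
              all(effects$comparison %in% c("comut_vs_wt",
                                            "tp53only_vs_wt")))
  }
  structure(list(n_lines = n_lines, lineages = lineages,
                 lineage_props = lineage_props,
                 genotype_props = genotype_props, n_features = n_features,
                 sources = sources, effects = effects, noise_sd = noise_sd,
                 lineage_sd = lineage_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cellline_sim_config")
}

#' Simulate a cell-line panel with feature matrices and ground truth
#'
#' Feature value = per-(lineage, feature) baseline + genotype effect +
#' Gaussian noise. Genotype effects come from the configured effect
#' table: a `comut_vs_wt` effect shifts co-mutant lines, a
#' `tp53only_vs_wt` effect shifts TP53-only lines.
#'
#' @param config A [cellline_sim_config()].
#' @return List of class `cellline_sim`: `panel` (data.table
#'   `cell_line_id`, `lineage`, `genotype`), `matrices` (named list of
#'   lines x features matrices), `ground_truth` (the effect table, zero
#'   rows when no effects configured).
#' @export
simulate_cellline_panel <- function(config) {
  stopifnot(inherits(config, "cellline_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # panel composition is part of the study conditions: realize the
  # configured proportions as exact counts (largest-remainder rounding),
  # randomly interleaved, rather than leaving group sizes to a
  # multinomial draw
  fixed_counts <- function(props, n) {
    k <- floor(props * n)
    rem <- order(props * n - k, decreasing = TRUE)
    k[rem[seq_len(n - sum(k))]] <- k[rem[seq_len(n - sum(k))]] + 1L
    k
  }
  gp <- config$genotype_props
  lp <- stats::setNames(config$lineage_props, config$lineages)
  panel <- data.table(
    cell_line_id = sprintf("CL%04d", seq_len(config$n_lines)),
    lineage = sample(rep(names(lp), fixed_counts(lp, config$n_lines))),
    genotype = sample(rep(names(gp), fixed_counts(gp, config$n_lines))))

  matrices <- lapply(config$sources, function(src) {
    feats <- sprintf("%s_f%04d", src, seq_len(config$n_features))
    base <- matrix(stats::rnorm(length(config$lineages) *
                                  config$n_features, 0, config$lineage_sd),
                   length(config$lineages), config$n_features,
                   dimnames = list(config$lineages, feats))
    m <- base[panel$lineage, , drop = FALSE] +
      matrix(stats::rnorm(config$n_lines * config$n_features, 0,
                          config$noise_sd),
             config$n_lines, config$n_features)
    dimnames(m) <- list(panel$cell_line_id, feats)
    if (!is.null(config$effects)) {
      ef <- config$effects[feature %in% feats]
      for (k in seq_len(nrow(ef))) {
        cls <- if (ef$comparison[k] == "comut_vs_wt") "comut" else
          "tp53_only"
        rows <- panel$genotype == cls
        m[rows, ef$feature[k]] <- m[rows, ef$feature[k]] + ef$effect[k]
      }
    }
    if (config$missing_rate > 0)
      m[stats::runif(length(m)) < config$missing_rate] <- NA_real_
    m
  })
  names(matrices) <- config$sources
  ground_truth <- if (is.null(config$effects))
    data.table(feature = character(), comparison = character(),
               effect = numeric()) else data.table::copy(config$effects)
  structure(list(panel = panel, matrices = matrices,
                 ground_truth = ground_truth, config = config),
            class = "cellline_sim")
}
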