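# Co-mutation screen: per (gene pair, cancer type) 2x2 tables, directional
# hypergeometric-tail Fisher tests, BH adjustment, and the three summary
# tables (per pair, per cancer type, full grid).

#' Build a 2x2 co-alteration contingency table
#'
#' Partitions a case set into co-altered / gene1-only / gene2-only /
#' neither, given per-case alteration indicators for both genes.
#'
#' @param altered1,altered2 Logical vectors, one element per case.
#' @return List of class `contingency_counts` with `comutant`, `g1_only`,
#'   `g2_only`, `neither`, derived margins `g1_mutant`, `g2_mutant`,
#'   `total`, and fractions `co_frac`, `g1_frac`, `g2_frac` (NA when
#'   `total == 0`).
#' @export
build_contingency <- function(altered1, altered2) {
  stopifnot(is.logical(altered1), is.logical(altered2),
            length(altered1) == length(altered2))
  comutant <- sum(altered1 & altered2)
  g1_only <- sum(altered1 & !altered2)
  g2_only <- sum(!altered1 & altered2)
  neither <- sum(!altered1 & !altered2)
  total <- comutant + g1_only + g2_only + neither
  structure(list(
    comutant = comutant, g1_only = g1_only, g2_only = g2_only,
    neither = neither,
    g1_mutant = comutant + g1_only, g2_mutant = comutant + g2_only,
    total = total,
    co_frac = if (total > 0) comutant / total else NA_real_,
    g1_frac = if (total > 0) (comutant + g1_only) / total else NA_real_,
    g2_frac = if (total > 0) (comutant + g2_only) / total else NA_real_
  ), class = "contingency_counts")
}

#' One-tailed Fisher exact test on a co-alteration table
#'
#' The conditional null given both margins is hypergeometric:
#' `X ~ Hypergeom(total, g1_mutant, g2_mutant)` counts co-altered cases.
#' The concurrent (enrichment) p-value is the upper tail
#' `P(X >= comutant)`; the exclusive (depletion) p-value is the lower tail
#' `P(X <= comutant)`. Degenerate margins (either gene altered in no case
#' or in every case) carry p = 1 in both directions — conservative and
#' order-independent. All arguments vectorize.
#'
#' @param comutant,g1_mutant,g2_mutant,total Table counts (margins and
#'   co-altered cell); alternatively pass a `contingency_counts` as
#'   `comutant` with the others missing.
#' @param direction `"concurrent"` or `"exclusive"`.
#' @return Numeric p-value(s) in (0, 1].
#' @export
fisher_one_tailed <- function(comutant, g1_mutant, g2_mutant, total,
                              direction = c("concurrent", "exclusive")) {
  if (inherits(comutant, "contingency_counts")) {
    cc <- comutant
    comutant <- cc$comutant; g1_mutant <- cc$g1_mutant
    g2_mutant <- cc$g2_mutant; total <- cc$total
  }
  direction <- match.arg(direction)
  stopifnot(all(total >= 1), all(comutant >= 0),
            all(g1_mutant <= total), all(g2_mutant <= total))
  p <- if (direction == "concurrent")
    phyper(comutant - 1L, g1_mutant, total - g1_mutant, g2_mutant,
           lower.tail = FALSE)
  else
    phyper(comutant, g1_mutant, total - g1_mutant, g2_mutant)
  degenerate <- g1_mutant == 0L | g2_mutant == 0L |
    g1_mutant == total | g2_mutant == total
  p[degenerate] <- 1
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg step-up adjustment over a declared family
#'
#' Standard BH step-up, with an explicit family size so that skipped or
#' degenerate tests can be counted in the family (they behave as p = 1 at
#' the top of the ranking and never alter the step-up minimum of the
#' observed values).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family_size Number of tests in the family; must be at least
#'   `length(p)`.
#' @return Adjusted p-values, same order as input, clipped to `[0, 1]`.
#' @export
bh_adjust <- function(p, family_size = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(family_size >= length(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH", n = family_size)
}

#' Expected co-alteration fraction under independence
#'
#' Product of the two marginal alteration fractions; the background
#' expectation against which an observed co-alteration fraction is judged
#' in the pair scatter view.
#'
#' @param g1_frac,g2_frac Marginal fractions, or a `contingency_counts`
#'   as the first argument.
#' @return Numeric in `[0, 1]`.
#' @export
independence_expectation <- function(g1_frac, g2_frac) {
  if (inherits(g1_frac, "contingency_counts")) {
    cc <- g1_frac
    g1_frac <- cc$g1_frac; g2_frac <- cc$g2_frac
  }
  g1_frac * g2_frac
}

# Per-pair stratified counts for one gene pair, restricted to covered
# cases. Returns one row per cancer type present among covered cases.
pair_counts <- function(g1, g2, alt_mat, panels, cases) {
  cov <- cases_covering(c(g1, g2), panels, cases)
  if (nrow(cov) == 0L) return(NULL)
  a1 <- alt_mat[g1, cov$sample_id]
  a2 <- alt_mat[g2, cov$sample_id]
  dt <- data.table(cancer_type = cov$cancer_type_detailed,
                   both = a1 & a2, m1 = a1, m2 = a2)
  dt[, .(comutant = sum(both), g1_mutant = sum(m1), g2_mutant = sum(m2),
         total = .N), by = cancer_type]
}

#' Run the pan-cancer co-mutation screen
#'
#' For every unordered pair from `gene_list`: restrict cases to panels
#' covering both genes, stratify by detailed cancer type, build the 2x2
#' table per stratum, test both directions with [fisher_one_tailed()],
#' and BH-adjust. Strata below `min_cases` and degenerate strata stay in
#' the BH family (the former with no p-value, the latter at p = 1).
#'
#' @param registry A `comut_registry`.
#' @param gene_list Character vector of >= 2 gene symbols to screen.
#' @param alterations Optional `alteration_set` (from
#'   [integrate_alterations()]); default uses mutation calls only.
#' @param alpha Significance level for the `*.sig` flags (default 0.05).
#' @param min_cases Minimum stratum size to test (default 0).
#' @param bh_scope `"per_pair"` (adjust across cancer types within one
#'   pair and direction) or `"global"` (across the full pair x type grid
#'   per direction).
#' @return List of class `comut_screen` with data.tables `full_results`,
#'   `pair_summary`, `cancer_type_summary`, plus the call parameters.
#' @export
run_screen <- function(registry, gene_list, alterations = NULL,
                       alpha = 0.05, min_cases = 0,
                       bh_scope = c("per_pair", "global")) {
  bh_scope <- match.arg(bh_scope)
  gene_list <- sort(unique(toupper(gene_list)))
  if (length(gene_list) < 2L) stop("gene_list needs at least two genes")
  if (is.null(alterations))
    alterations <- integrate_alterations(
      registry, policy = integration_policy(FALSE, FALSE, cgc_gated = FALSE))
  alt_mat <- alteration_matrix(alterations, gene_list,
                               registry$cases$sample_id)
  pairs <- enumerate_pairs(gene_list)

  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    ct <- pair_counts(g1, g2, alt_mat, registry$panels, registry$cases)
    if (is.null(ct)) {
      res[[i]] <- data.table(gene1 = g1, gene2 = g2,
                             cancer_type = NA_character_, comutant = NA_integer_,
                             g1_mutant = NA_integer_, g2_mutant = NA_integer_,
                             total = 0L, tested = FALSE)
      next
    }
    ct[, `:=`(gene1 = g1, gene2 = g2, tested = total >= min_cases)]
    res[[i]] <- ct
  }
  full <- data.table::rbindlist(res, use.names = TRUE, fill = TRUE)
  data.table::setorder(full, gene1, gene2, cancer_type, na.last = TRUE)

  full[, `:=`(co.frac = ifelse(total > 0, comutant / total, NA_real_),
              g1.frac = ifelse(total > 0, g1_mutant / total, NA_real_),
              g2.frac = ifelse(total > 0, g2_mutant / total, NA_real_))]
  full[, expected.co.frac := g1.frac * g2.frac]
  full[, `:=`(concurrent.pv = NA_real_, exclusive.pv = NA_real_)]
  full[tested == TRUE,
       `:=`(concurrent.pv = fisher_one_tailed(comutant, g1_mutant, g2_mutant,
                                              total, "concurrent"),
            exclusive.pv = fisher_one_tailed(comutant, g1_mutant, g2_mutant,
                                             total, "exclusive"))]

  # BH family: all strata enumerated for the pair (tested or not).
  full[, `:=`(concurrent.padj = NA_real_, exclusive.padj = NA_real_)]
  if (bh_scope == "per_pair") {
    full[!is.na(cancer_type),
         `:=`(concurrent.padj = {
           fam <- .N
           out <- rep(NA_real_, .N)
           out[tested] <- bh_adjust(concurrent.pv[tested], fam)
           out
         },
         exclusive.padj = {
           fam <- .N
           out <- rep(NA_real_, .N)
           out[tested] <- bh_adjust(exclusive.pv[tested], fam)
           out
         }),
         by = .(gene1, gene2)]
  } else {
    strata <- full[!is.na(cancer_type)]
    fam <- nrow(strata)
    full[!is.na(cancer_type) & tested == TRUE,
         `:=`(concurrent.padj = bh_adjust(concurrent.pv, fam),
              exclusive.padj = bh_adjust(exclusive.pv, fam))]
  }

  full[, `:=`(
    concurrent.pv.sig = !is.na(concurrent.pv) & concurrent.pv < alpha,
    concurrent.padj.sig = !is.na(concurrent.padj) & concurrent.padj < alpha,
    exclusive.pv.sig = !is.na(exclusive.pv) & exclusive.pv < alpha,
    exclusive.padj.sig = !is.na(exclusive.padj) & exclusive.padj < alpha)]

  data.table::setcolorder(full, c(
    "gene1", "gene2", "cancer_type", "comutant", "g1_mutant", "g2_mutant",
    "total", "co.frac", "g1.frac", "g2.frac", "expected.co.frac",
    "concurrent.pv", "concurrent.padj", "exclusive.pv", "exclusive.padj",
    "concurrent.pv.sig", "concurrent.padj.sig", "exclusive.pv.sig",
    "exclusive.padj.sig", "tested"))

  pair_summary <- full[!is.na(cancer_type), .(
    overall.comut.frac = sum(comutant) / sum(total),
    total.comutant = sum(comutant),
    n.types.tested = sum(tested),
    concurrent.pv.sig = sum(concurrent.pv.sig),
    concurrent.padj.sig = sum(concurrent.padj.sig),
    exclusive.pv.sig = sum(exclusive.pv.sig),
    exclusive.padj.sig = sum(exclusive.padj.sig)
  ), by = .(gene1, gene2)]
  untested <- full[is.na(cancer_type), .(gene1, gene2)]
  if (nrow(untested)) {
    pair_summary <- data.table::rbindlist(list(
      pair_summary,
      untested[, .(gene1, gene2, overall.comut.frac = NA_real_,
                   total.comutant = 0L, n.types.tested = 0L,
                   concurrent.pv.sig = 0L, concurrent.padj.sig = 0L,
                   exclusive.pv.sig = 0L, exclusive.padj.sig = 0L)]),
      use.names = TRUE)
  }
  data.table::setorder(pair_summary, gene1, gene2)

  cancer_type_summary <- full[!is.na(cancer_type), .(
    n.sig.pairs = sum(concurrent.padj.sig),
    avg.total = mean(total)
  ), by = cancer_type][order(cancer_type)]

  structure(list(full_results = full, pair_summary = pair_summary,
                 cancer_type_summary = cancer_type_summary,
                 alpha = alpha, min_cases = min_cases, bh_scope = bh_scope,
                 gene_list = gene_list),
            class = "comut_screen")
}

#' @export
print.comut_screen <- function(x, ...) {
  cat(sprintf(paste0("<comut_screen> %d pairs x %d cancer types; ",
                     "%d strata tested, %d concurrent padj<%.2g\n"),
              nrow(x$pair_summary),
              nrow(x$cancer_type_summary),
              sum(x$full_results$tested, na.rm = TRUE),
              sum(x$full_results$concurrent.padj.sig, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Rank gene pairs by co-mutation diversity
#'
#' Orders pairs by the number of cancer types with BH-significant
#' concurrent enrichment, then by total co-altered cases, ties broken
#' lexicographically by (gene1, gene2). A pair enriched across many
#' lineages ranks above one dominated by a single lineage.
#'
#' @param screen A `comut_screen` result (or its `pair_summary`).
#' @return `pair_summary` rows in rank order with a `rank` column.
#' @export
diversity_ranking <- function(screen) {
  ps <- if (inherits(screen, "comut_screen")) screen$pair_summary else screen
  ps <- data.table::copy(ps)
  data.table::setorderv(ps,
                        c("concurrent.padj.sig", "total.comutant", "gene1", "gene2"),
                        order = c(-1L, -1L, 1L, 1L))
  ps[, rank := seq_len(.N)]
  ps[]
}
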