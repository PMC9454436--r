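# Clinical associations of the co-altered oncogenotype: per-cancer-type
# directional Fisher tests against vital status or sample type,
# per-genotype death rates, and rank-based comparison of co-mutation
# frequency across cancer-type categories.

outcome_spec <- list(
  vital = list(column = "vital_status",
               positive = c(enriched_in_dead = "dead",
                            enriched_in_alive = "alive")),
  sample_type = list(column = "sample_type",
                     positive = c(enriched_in_metastasis = "metastasis",
                                  enriched_in_primary = "primary"))
)

#' Association between co-alteration and a clinical outcome per cancer type
#'
#' Within each detailed cancer type, tests the 2x2 table of co-altered
#' vs. all other genotypes against the dichotomized outcome with a
#' one-tailed Fisher test in the requested direction, then BH-adjusts
#' across cancer types within the direction. Cases with unknown outcome
#' are excluded before table construction; cancer types left with no
#' informative case are skipped but stay in the BH family.
#'
#' @param cases Case table (one row per case, covered for the pair).
#' @param genotypes Factor from [oncogenotype()], aligned with `cases`.
#' @param outcome `"vital"` or `"sample_type"`.
#' @param direction For vital: `"enriched_in_dead"` / `"enriched_in_alive"`;
#'   for sample type: `"enriched_in_metastasis"` / `"enriched_in_primary"`.
#' @param alpha Significance level for flags (default 0.05).
#' @return data.table per cancer type: counts `comut_pos`, `comut_neg`,
#'   `other_pos`, `other_neg`, `p`, `padj`, `sig`, plus `direction` and
#'   attribute `"family_size"`.
#' @export
outcome_association <- function(cases, genotypes,
                                outcome = c("vital", "sample_type"),
                                direction, alpha = 0.05) {
  outcome <- match.arg(outcome)
  spec <- outcome_spec[[outcome]]
  direction <- match.arg(direction, names(spec$positive))
  stopifnot(nrow(cases) == length(genotypes))
  pos_level <- spec$positive[[direction]]

  dt <- data.table(cancer_type = cases$cancer_type_detailed,
                   outcome = cases[[spec$column]],
                   comut = genotypes == "comut")
  all_types <- sort(unique(dt$cancer_type))
  dt <- dt[outcome != "unknown"]
  tab <- dt[, .(comut_pos = sum(comut & outcome == pos_level),
                comut_neg = sum(comut & outcome != pos_level),
                other_pos = sum(!comut & outcome == pos_level),
                other_neg = sum(!comut & outcome != pos_level)),
            by = cancer_type]
  tab <- tab[comut_pos + comut_neg + other_pos + other_neg > 0]
  family <- length(all_types)

  if (nrow(tab)) {
    # conditional hypergeometric: X = co-altered cases among the
    # positive-outcome margin; enrichment is the upper tail
    tab[, p := fisher_one_tailed(
      comutant = comut_pos,
      g1_mutant = comut_pos + comut_neg,
      g2_mutant = comut_pos + other_pos,
      total = comut_pos + comut_neg + other_pos + other_neg,
      direction = "concurrent")]
    tab[, padj := bh_adjust(p, family_size = family)]
    tab[, sig := padj < alpha]
  } else {
    tab <- data.table(cancer_type = character(), comut_pos = integer(),
                      comut_neg = integer(), other_pos = integer(),
                      other_neg = integer(), p = numeric(),
                      padj = numeric(), sig = logical())
  }
  tab[, direction := direction]
  data.table::setorder(tab, p, cancer_type, na.last = TRUE)
  data.table::setattr(tab, "family_size", family)
  tab[]
}

#' Death rate per oncogenotype and cancer type
#'
#' Cases with unknown vital status are excluded from the denominators.
#' Empty genotype classes are emitted with `n = 0` and missing rate.
#'
#' @param cases Case table aligned with `genotypes`.
#' @param genotypes Factor from [oncogenotype()].
#' @return data.table: `cancer_type`, `genotype`, `n` (informative
#'   cases), `n_dead`, `death_rate` (NA when `n == 0`).
#' @export
oncogenotype_death_rates <- function(cases, genotypes) {
  stopifnot(nrow(cases) == length(genotypes))
  dt <- data.table(cancer_type = cases$cancer_type_detailed,
                   vital = cases$vital_status, genotype = genotypes)
  dt <- dt[vital != "unknown"]
  grid <- data.table::CJ(cancer_type = unique(dt$cancer_type),
                         genotype = levels(genotypes))
  agg <- dt[, .(n = .N, n_dead = sum(vital == "dead")),
            by = .(cancer_type, genotype = as.character(genotype))]
  out <- merge(grid, agg, by = c("cancer_type", "genotype"), all.x = TRUE)
  out[is.na(n), `:=`(n = 0L, n_dead = 0L)]
  out[, death_rate := ifelse(n > 0, n_dead / n, NA_real_)]
  data.table::setorder(out, cancer_type, genotype)
  out[]
}

#' Default cancer-type category rules
#'
#' Case-insensitive substring rules mapping detailed cancer-type names to
#' the categories compared in the frequency analysis; first match wins,
#' anything unmatched is `"other"`.
#'
#' @return Named list of character vectors of substrings.
#' @export
default_category_rules <- function() {
  list(small_cell = "small cell",
       neuroendocrine = "neuroendocrine",
       sarcoma = "sarcoma")
}

#' Assign cancer types to categories by name-pattern rules
#'
#' @param cancer_types Character vector of detailed cancer-type names.
#' @param rules Named list of substring vectors; see
#'   [default_category_rules()].
#' @return Factor with levels `names(rules)` plus `"other"`.
#' @export
assign_categories <- function(cancer_types, rules = default_category_rules()) {
  out <- rep("other", length(cancer_types))
  low <- tolower(cancer_types)
  for (cat in rev(names(rules))) {  # first rule in list wins
    hit <- Reduce(`|`, lapply(tolower(rules[[cat]]),
                              function(p) grepl(p, low, fixed = TRUE)))
    out[hit] <- cat
  }
  factor(out, levels = c(names(rules), "other"))
}

#' Compare per-cancer-type co-mutation fractions across categories
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) test of each selected
#' category against the `"other"` category, testing whether the selected
#' category's co-mutation fractions are stochastically larger. Exact tail
#' probabilities are used for small comparisons (m * n <= 400, no ties);
#' larger or tied comparisons use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param fractions Numeric vector of per-cancer-type co-mutation
#'   fractions.
#' @param categories Factor from [assign_categories()], aligned with
#'   `fractions`.
#' @return data.table: `category`, `n`, `n_other`, `p`.
#' @export
category_comparison <- function(fractions, categories) {
  stopifnot(length(fractions) == length(categories))
  other <- fractions[categories == "other"]
  cats <- setdiff(levels(categories), "other")
  rows <- lapply(cats, function(cat) {
    grp <- fractions[categories == cat]
    if (length(grp) == 0L || length(other) == 0L) {
      warning("category comparison skipped for '", cat,
              "': empty group")
      return(data.table(category = cat, n = length(grp),
                        n_other = length(other), p = NA_real_))
    }
    exact <- length(grp) * length(other) <= 400 &&
      !anyDuplicated(c(grp, other))
    p <- suppressWarnings(
      wilcox.test(grp, other, alternative = "greater",
                  exact = exact, correct = TRUE)$p.value)
    data.table(category = cat, n = length(grp), n_other = length(other), p = p)
  })
  data.table::rbindlist(rows)[]
}
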