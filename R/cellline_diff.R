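# Lineage-adjusted differential feature analysis on cell-line panels:
# per feature, ordinary least squares of feature ~ lineage + mutation
# status; the mutation-term estimate, t statistic and two-sided p-value
# are recorded and BH-adjusted within each data source.

#' Fit the lineage-adjusted mutation model for one feature
#'
#' Ordinary least squares of `value ~ intercept + lineage + mutant` on
#' the cell lines with an observed value. Lineage dummies are rebuilt on
#' the retained lines, so lineages emptied by missingness drop out.
#'
#' @param values Numeric feature values, NA = not measured.
#' @param lineage Character/factor lineage per line.
#' @param mutant Logical mutation status per line.
#' @param min_per_group Minimum retained lines required in each of the
#'   mutant and wild-type groups (default 3).
#' @return List: `coefficient`, `t_value`, `p_value`, `n_used`, and
#'   `status` — `"ok"`; `"inestimable"` when the contrast cannot be
#'   estimated (one group absent/too small, or lineage perfectly
#'   confounded with mutation status); `"degenerate"` when the fit has
#'   zero residual variance (coefficient reported, no test).
#' @export
fit_feature_model <- function(values, lineage, mutant, min_per_group = 3) {
  stopifnot(length(values) == length(lineage),
            length(values) == length(mutant))
  keep <- !is.na(values) & !is.na(mutant) & !is.na(lineage)
  values <- values[keep]
  lineage <- droplevels(factor(lineage[keep]))
  mutant <- as.logical(mutant[keep])
  n <- length(values)
  fail <- function(status) list(coefficient = NA_real_, t_value = NA_real_,
                                p_value = NA_real_, n_used = n,
                                status = status)
  if (sum(mutant) < min_per_group || sum(!mutant) < min_per_group)
    return(fail("inestimable"))

  X <- if (nlevels(lineage) >= 2L)
    stats::model.matrix(~ lineage + mutant)
  else stats::model.matrix(~ mutant)
  fit <- stats::lm.fit(X, values)
  j <- match("mutantTRUE", names(fit$coefficients))
  est <- fit$coefficients[j]
  if (is.na(est) || fit$rank < ncol(X))  # aliased: lineage confounds status
    return(fail("inestimable"))
  df <- n - fit$rank
  if (df <= 0) return(fail("inestimable"))
  rss <- sum(fit$residuals^2)
  scale <- mean(values^2) + 1
  if (rss / scale < 1e-24) {
    out <- fail("degenerate")
    out$coefficient <- unname(est)
    return(out)
  }
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- unname(est / se)
  list(coefficient = unname(est), t_value = tval,
       p_value = 2 * pt(abs(tval), df, lower.tail = FALSE),
       n_used = n, status = "ok")
}

#' Differential feature screen for a genotype comparison
#'
#' Restricts the panel to the two genotype classes of the comparison
#' (co-mutant vs. double wild-type, or TP53-only vs. double wild-type;
#' RB1-only lines are excluded from both for lack of numbers), fits
#' [fit_feature_model()] per feature, and BH-adjusts within each data
#' source over the estimable features.
#'
#' @param panel data.table/data.frame with `cell_line_id`, `lineage`,
#'   `genotype` (levels `comut`, `rb1_only`, `tp53_only`, `wt`).
#' @param matrices Named list of numeric matrices (cell lines x
#'   features, rownames = cell line ids); names are the data sources.
#' @param comparison `"comut_vs_wt"` or `"tp53only_vs_wt"`.
#' @param min_per_group Passed to [fit_feature_model()].
#' @param alpha FDR threshold for the `sig` flag (default 0.10).
#' @return data.table: `feature`, `source`, `comparison`, `n_used`,
#'   `coefficient`, `t_value`, `p_value`, `fdr`, `sig`, `status`.
#' @export
run_differential <- function(panel, matrices,
                             comparison = c("comut_vs_wt", "tp53only_vs_wt"),
                             min_per_group = 3, alpha = 0.10) {
  comparison <- match.arg(comparison)
  panel <- data.table::as.data.table(panel)
  stopifnot(all(c("cell_line_id", "lineage", "genotype") %in% names(panel)))
  if (is.null(names(matrices)) || any(names(matrices) == ""))
    stop("matrices must be a named list (names = data sources)")
  mut_class <- if (comparison == "comut_vs_wt") "comut" else "tp53_only"
  sub <- panel[genotype %in% c(mut_class, "wt")]

  res <- lapply(names(matrices), function(src) {
    m <- matrices[[src]]
    lines <- intersect(sub$cell_line_id, rownames(m))
    sp <- sub[match(lines, cell_line_id)]
    rows <- lapply(colnames(m), function(f) {
      fit <- fit_feature_model(m[lines, f], sp$lineage,
                               sp$genotype == mut_class, min_per_group)
      data.table(feature = f, source = src, comparison = comparison,
                 n_used = fit$n_used, coefficient = fit$coefficient,
                 t_value = fit$t_value, p_value = fit$p_value,
                 status = fit$status)
    })
    data.table::rbindlist(rows)
  })
  out <- data.table::rbindlist(res)
  out[, fdr := NA_real_]
  out[status == "ok", fdr := bh_adjust(p_value), by = source]
  out[, sig := !is.na(fdr) & fdr < alpha]
  data.table::setorder(out, source, p_value, feature, na.last = TRUE)
  out[]
}

#' Group differential compound results by target pathway
#'
#' Keeps compounds at nominal `p < p_cutoff`, annotates each with its
#' pathway category and target from a compound map, and orders within
#' category by t-value. Unmapped compounds fall into `"uncategorized"`.
#'
#' @param diff_results Output of [run_differential()].
#' @param pathway_map data.table/data.frame with `feature`, `category`,
#'   optional `target`.
#' @param p_cutoff Nominal p-value filter (default 0.05).
#' @return data.table of the filtered rows with `category` and `target`.
#' @export
categorize_compounds <- function(diff_results, pathway_map = NULL,
                                 p_cutoff = 0.05) {
  out <- data.table::as.data.table(diff_results)[
    status == "ok" & !is.na(p_value) & p_value < p_cutoff]
  if (!is.null(pathway_map) && nrow(pathway_map)) {
    pm <- data.table::as.data.table(pathway_map)
    stopifnot(all(c("feature", "category") %in% names(pm)))
    if (!("target" %in% names(pm))) pm[, target := NA_character_]
    out <- merge(out, pm[, .(feature, category, target)],
                 by = "feature", all.x = TRUE, sort = FALSE)
  } else {
    out[, `:=`(category = NA_character_, target = NA_character_)]
  }
  out[is.na(category), category := "uncategorized"]
  data.table::setorder(out, category, -t_value, feature)
  out[]
}

#' Pair t-values of the two genotype comparisons per feature
#'
#' Merges per-feature results from the co-mutant vs. wild-type and the
#' TP53-only vs. wild-type comparisons for the scatter export.
#'
#' @param diff_comut,diff_tp53 Outputs of [run_differential()] for the
#'   two comparisons on the same matrices.
#' @return data.table keyed by (`feature`, `source`) with suffixed
#'   t/p/fdr columns `.comut` and `.tp53only`.
#' @export
comparison_scatter <- function(diff_comut, diff_tp53) {
  a <- data.table::as.data.table(diff_comut)[
    , .(feature, source, t.comut = t_value, p.comut = p_value,
        fdr.comut = fdr)]
  b <- data.table::as.data.table(diff_tp53)[
    , .(feature, source, t.tp53only = t_value, p.tp53only = p_value,
        fdr.tp53only = fdr)]
  merge(a, b, by = c("feature", "source"))[]
}
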