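# Fold discrete copy-number and fusion events into per-(gene, sample)
# alteration status. Copy-number events only count where the gene
# annotation (Cancer Gene Census style) permits that event class: loss
# needs mutation type "D", gain needs "A". Per-gene overrides let the
# caller re-include a gene the annotation misses (e.g. TP53 deletion).

#' Construct an alteration-integration policy
#'
#' @param use_cna Count copy-number events (default TRUE).
#' @param use_fusion Count fusion events (default TRUE).
#' @param cgc_gated Gate copy-number events on the gene annotation
#'   (default TRUE). Ungated, any loss/gain counts.
#' @param overrides Optional data.frame with columns `gene`,
#'   `allows_deletion`, `allows_amplification` (NA = leave annotation
#'   decision in place). Overrides win over the annotation.
#' @return List of class `integration_policy`.
#' @export
integration_policy <- function(use_cna = TRUE, use_fusion = TRUE,
                               cgc_gated = TRUE, overrides = NULL) {
  if (!is.null(overrides)) {
    overrides <- data.table::as.data.table(overrides)
    need <- c("gene", "allows_deletion", "allows_amplification")
    miss <- setdiff(need, names(overrides))
    if (length(miss)) stop("overrides missing column(s): ",
                           paste(miss, collapse = ", "))
    overrides[, gene := toupper(gene)]
  }
  structure(list(use_cna = isTRUE(use_cna), use_fusion = isTRUE(use_fusion),
                 cgc_gated = isTRUE(cgc_gated), overrides = overrides),
            class = "integration_policy")
}

# Effective per-gene permission table for a gene universe.
resolve_gating <- function(genes, cgc, policy) {
  genes <- unique(toupper(genes))
  if (!policy$cgc_gated) {
    gate <- data.table(gene = genes, allows_deletion = TRUE,
                       allows_amplification = TRUE)
  } else {
    gate <- data.table(gene = genes)
    if (!is.null(cgc)) {
      gate <- merge(gate, cgc, by = "gene", all.x = TRUE)
    } else {
      gate[, `:=`(allows_deletion = NA, allows_amplification = NA)]
    }
    unannotated <- gate$gene[is.na(gate$allows_deletion)]
    if (length(unannotated) && policy$use_cna)
      message("cgc gating: no annotation for ",
              paste(sort(unannotated), collapse = ", "),
              "; copy-number events disallowed unless overridden")
    gate[is.na(allows_deletion), allows_deletion := FALSE]
    gate[is.na(allows_amplification), allows_amplification := FALSE]
  }
  if (!is.null(policy$overrides)) {
    ov <- policy$overrides
    unknown <- setdiff(ov$gene, genes)
    if (length(unknown))
      stop("overrides reference unknown gene(s): ",
           paste(unknown, collapse = ", "))
    gate[ov, on = "gene",
         `:=`(allows_deletion = data.table::fifelse(
                is.na(i.allows_deletion), allows_deletion, i.allows_deletion),
              allows_amplification = data.table::fifelse(
                is.na(i.allows_amplification), allows_amplification,
                i.allows_amplification))]
  }
  gate
}

#' Integrate mutation, copy-number and fusion evidence per gene and case
#'
#' A (gene, sample) is altered when it carries a recorded mutation, or —
#' policy permitting — a copy-number value below zero (loss; includes -1
#' and -2) where deletion is allowed for the gene, a value above zero
#' where amplification is allowed, or a fusion event. Samples absent from
#' the copy-number matrix contribute no copy-number evidence but remain
#' assessable on mutations. Component flags are kept for provenance;
#' `altered` is a pure function of the flags, the gating table and the
#' policy.
#'
#' @param registry A `comut_registry` (uses `mutations`, `cna`, `fusions`,
#'   `cases`).
#' @param cgc Optional annotation table from [read_cgc()].
#' @param policy An [integration_policy()].
#' @param genes Optional gene universe; defaults to all genes seen in any
#'   evidence source.
#' @return data.table of class `alteration_set` with one row per
#'   (gene, sample) carrying any evidence: columns `gene`, `sample_id`,
#'   `mutated`, `cna_loss`, `cna_amp`, `fused`, `altered`. The policy is
#'   attached as attribute `"policy"`.
#' @export
integrate_alterations <- function(registry, cgc = NULL,
                                  policy = integration_policy(),
                                  genes = NULL) {
  mut <- registry$mutations
  cna <- registry$cna
  fus <- registry$fusions
  if (nrow(cna) && any(!(cna$value %in% -2:2)))
    stop("copy-number value outside {-2,...,2}")
  if (is.null(genes))
    genes <- unique(c(mut$gene, cna$gene, fus$gene))
  genes <- unique(toupper(genes))

  ev <- data.table::rbindlist(list(
    mut[gene %in% genes, .(gene, sample_id, mutated = TRUE,
                           cna_loss = FALSE, cna_amp = FALSE, fused = FALSE)],
    cna[gene %in% genes & value < 0,
        .(gene, sample_id, mutated = FALSE, cna_loss = TRUE,
          cna_amp = FALSE, fused = FALSE)],
    cna[gene %in% genes & value > 0,
        .(gene, sample_id, mutated = FALSE, cna_loss = FALSE,
          cna_amp = TRUE, fused = FALSE)],
    fus[gene %in% genes, .(gene, sample_id, mutated = FALSE,
                           cna_loss = FALSE, cna_amp = FALSE, fused = TRUE)]
  ), use.names = TRUE)
  if (nrow(ev) == 0L) {
    out <- data.table(gene = character(), sample_id = character(),
                      mutated = logical(), cna_loss = logical(),
                      cna_amp = logical(), fused = logical(),
                      altered = logical())
    data.table::setattr(out, "policy", policy)
    data.table::setattr(out, "class", c("alteration_set", class(out)))
    return(out)
  }
  out <- ev[, .(mutated = any(mutated), cna_loss = any(cna_loss),
                cna_amp = any(cna_amp), fused = any(fused)),
            by = .(gene, sample_id)]

  gate <- resolve_gating(genes, cgc, policy)
  out <- merge(out, gate, by = "gene", all.x = TRUE, sort = FALSE)
  out[, altered := mutated |
        (policy$use_cna & cna_loss & allows_deletion) |
        (policy$use_cna & cna_amp & allows_amplification) |
        (policy$use_fusion & fused)]
  out[, c("allows_deletion", "allows_amplification") := NULL]
  data.table::setorder(out, gene, sample_id)
  data.table::setattr(out, "policy", policy)
  data.table::setattr(out, "class", c("alteration_set", class(out)))
  out[]
}

#' Dense logical alteration matrix
#'
#' @param alterations An `alteration_set`.
#' @param genes Row universe (gene symbols).
#' @param samples Column universe (sample ids).
#' @return Logical matrix genes x samples; TRUE where altered.
#' @export
alteration_matrix <- function(alterations, genes, samples) {
  genes <- unique(toupper(genes))
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  hit <- alterations[altered == TRUE & gene %in% genes & sample_id %in% samples]
  if (nrow(hit)) m[cbind(hit$gene, hit$sample_id)] <- TRUE
  m
}

#' Classify cases into the four oncogenotypes of a gene pair
#'
#' @param alterations An `alteration_set`.
#' @param pair Character vector of two distinct gene symbols.
#' @param cases Case table (already coverage-restricted for the pair).
#' @return Factor with levels `comut`, `g1_only`, `g2_only`, `wt`, one
#'   element per case, names = sample ids.
#' @export
oncogenotype <- function(alterations, pair, cases) {
  pair <- toupper(pair)
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  m <- alteration_matrix(alterations, pair, cases$sample_id)
  a1 <- m[pair[1], ]; a2 <- m[pair[2], ]
  g <- data.table::fifelse(a1 & a2, "comut",
        data.table::fifelse(a1, "g1_only",
          data.table::fifelse(a2, "g2_only", "wt")))
  out <- factor(g, levels = c("comut", "g1_only", "g2_only", "wt"))
  names(out) <- cases$sample_id
  out
}
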