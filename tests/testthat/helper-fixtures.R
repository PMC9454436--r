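# Fixture builders: all inputs are written programmatically at test time.

write_lines_tsv <- function(lines, path) {
  writeLines(lines, path)
  path
}

# Minimal 3-sample registry: two panels, one mutation row per sample,
# a CNA matrix and one fusion.
make_mini_registry_files <- function(dir = tempfile("reg")) {
  dir.create(dir)
  list(
    clinical = write_lines_tsv(c(
      "SAMPLE_ID\tPATIENT_ID\tCANCER_TYPE_DETAILED\tDEAD\tSAMPLE_TYPE\tSEQ_ASSAY_ID",
      "S1\tP1\tLung Adenocarcinoma\tTrue\tPrimary\tPAN1",
      "S2\tP2\tLung Adenocarcinoma\tFalse\tMetastasis\tPAN1",
      "S3\tP3\tSmall Cell Lung Cancer\t\t\tPAN2"),
      file.path(dir, "clinical.tsv")),
    mutations = write_lines_tsv(c(
      "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
      "TP53\tS1\tMissense_Mutation",
      "RB1\tS1\tNonsense_Mutation",
      "TP53\tS2\tSplice_Site",
      "KRAS\tS3\tMissense_Mutation"),
      file.path(dir, "mutations.tsv")),
    panels = write_lines_tsv(c(
      "SEQ_ASSAY_ID\tHugo_Symbol",
      "PAN1\tTP53", "PAN1\tRB1", "PAN1\tKRAS",
      "PAN2\tTP53", "PAN2\tKRAS"),
      file.path(dir, "panels.tsv")),
    cna = write_lines_tsv(c(
      "Hugo_Symbol\tS1\tS2\tS3",
      "RB1\t-2\t0\t",
      "TP53\t0\t-1\t1"),
      file.path(dir, "cna.tsv")),
    fusions = write_lines_tsv(c(
      "Hugo_Symbol\tTumor_Sample_Barcode",
      "RB1\tS2"),
      file.path(dir, "fusions.tsv")),
    cgc = write_lines_tsv(c(
      "GENE_SYMBOL\tMUTATION_TYPES",
      "RB1\tD,N,F", "TP53\tN,F", "KRAS\tA,Mis"),
      file.path(dir, "cgc.tsv")),
    dir = dir
  )
}

# 12-case hand-built integration fixture exercising the loss rules:
# mutation, CN < 0 with/without "D" permission, fusion, amplification
# gating, and the TP53-deletion override case.
make_integration_fixture <- function() {
  samples <- sprintf("C%02d", 1:12)
  cases <- data.table::data.table(
    sample_id = samples, patient_id = samples,
    cancer_type_detailed = rep(c("typeA", "typeB"), each = 6),
    vital_status = rep(c("dead", "alive"), 6),
    sample_type = rep("primary", 12), assay_id = "PANX")
  panels <- panel_registry(list(PANX = c("RB1", "TP53", "KRAS")))
  mutations <- data.table::data.table(
    gene = c("RB1", "TP53", "TP53"),
    sample_id = c("C01", "C01", "C02"),
    variant_class = "Missense_Mutation")
  cna <- data.table::data.table(
    gene   = c("RB1", "RB1", "TP53", "TP53", "KRAS", "KRAS", "RB1"),
    sample_id = c("C03", "C04", "C05", "C06", "C07", "C08", "C09"),
    value  = c(-2L, -1L, -1L, -2L, 1L, -1L, 2L))
  fusions <- data.table::data.table(
    gene = c("RB1", "TP53"), sample_id = c("C10", "C11"))
  registry <- structure(
    list(panels = panels, cases = cases, mutations = mutations,
         cna = cna, fusions = fusions,
         dropped = c(mutations = 0L, cna = 0L, fusions = 0L)),
    class = "comut_registry")
  # CGC: RB1 permits deletion, TP53 does not (no "D"), KRAS permits
  # amplification only.
  cgc <- data.table::data.table(
    gene = c("RB1", "TP53", "KRAS"),
    allows_deletion = c(TRUE, FALSE, FALSE),
    allows_amplification = c(FALSE, FALSE, TRUE))
  list(registry = registry, cgc = cgc)
}

# In-memory registry from explicit per-case alteration patterns; one
# panel covering everything, one cancer type unless given.
make_manual_registry <- function(mut_genes_by_sample,
                                 cancer_types = NULL,
                                 vital = NULL, stype = NULL,
                                 genes = NULL) {
  samples <- names(mut_genes_by_sample)
  if (is.null(genes))
    genes <- sort(unique(unlist(mut_genes_by_sample)))
  if (is.null(cancer_types)) cancer_types <- rep("typeA", length(samples))
  if (is.null(vital)) vital <- rep("unknown", length(samples))
  if (is.null(stype)) stype <- rep("unknown", length(samples))
  cases <- data.table::data.table(
    sample_id = samples, patient_id = samples,
    cancer_type_detailed = cancer_types, vital_status = vital,
    sample_type = stype, assay_id = "PANEL")
  mut <- data.table::rbindlist(lapply(samples, function(s) {
    g <- mut_genes_by_sample[[s]]
    if (length(g) == 0L) return(NULL)
    data.table::data.table(gene = g, sample_id = s,
                           variant_class = "Missense_Mutation")
  }))
  if (is.null(mut) || nrow(mut) == 0L)
    mut <- data.table::data.table(gene = character(),
                                  sample_id = character(),
                                  variant_class = character())
  structure(list(
    panels = panel_registry(stats::setNames(list(genes), "PANEL")),
    cases = cases, mutations = mut,
    cna = data.table::data.table(gene = character(),
                                 sample_id = character(),
                                 value = integer()),
    fusions = data.table::data.table(gene = character(),
                                     sample_id = character()),
    dropped = c(mutations = 0L, cna = 0L, fusions = 0L)),
    class = "comut_registry")
}
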