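# Registry domain model: gene panels, clinical cases, mutation / CNA /
# fusion records, and the tab-separated dialects they are exchanged in.
# All tables are data.tables; the bundle returned by read_registry() is a
# light S3 list with validated foreign keys.

VITAL_LEVELS <- c("alive", "dead", "unknown")
SAMPLE_TYPE_LEVELS <- c("primary", "metastasis", "unknown")

#' Default normalization map for vital-status strings
#'
#' Raw registry exports encode death as free-ish text ("True"/"False",
#' blank, "Not Collected"). Normalization is by explicit lookup, never
#' guessed: strings absent from the map become `"unknown"`.
#'
#' @return Named character vector mapping lower-cased raw strings to
#'   `"alive"`, `"dead"` or `"unknown"`.
#' @export
default_vital_map <- function() {
  m <- c("true" = "dead", "false" = "alive", "dead" = "dead",
         "alive" = "alive", "not collected" = "unknown",
         "unknown" = "unknown")
  m <- c(m, "unknown")
  names(m)[length(m)] <- ""   # blank cell -> unknown
  m
}

#' Default normalization map for sample-type strings
#' @return Named character vector mapping lower-cased raw strings to
#'   `"primary"`, `"metastasis"` or `"unknown"`.
#' @export
default_sample_type_map <- function() {
  m <- c("primary" = "primary", "metastasis" = "metastasis",
         "unspecified" = "unknown", "not applicable" = "unknown",
         "unknown" = "unknown")
  m <- c(m, "unknown")
  names(m)[length(m)] <- ""   # blank cell -> unknown
  m
}

normalize_enum <- function(x, map, levels) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  out <- unname(map[x])
  out[is.na(out) | !(out %in% levels)] <- "unknown"
  out
}

#' Construct a panel registry
#'
#' A panel registry maps each sequencing assay id to the set of gene
#' symbols its panel covers. Symbols are upper-cased and de-duplicated;
#' the panel is the unit of coverage for every downstream denominator.
#'
#' @param panels Named list; names are assay ids, elements are character
#'   vectors of gene symbols.
#' @return A `panel_registry` (named list of character vectors).
#' @export
panel_registry <- function(panels) {
  if (!is.list(panels) || is.null(names(panels)) || any(names(panels) == ""))
    stop("panels must be a named list of gene vectors")
  if (anyDuplicated(names(panels)))
    stop("duplicate assay_id in panel registry: ",
         paste(unique(names(panels)[duplicated(names(panels))]), collapse = ", "))
  panels <- lapply(panels, function(g) {
    g <- unique(toupper(trimws(as.character(g))))
    g <- g[nzchar(g)]
    if (length(g) == 0L) stop("panel with empty gene set")
    sort(g)
  })
  structure(panels, class = "panel_registry")
}

#' @export
print.panel_registry <- function(x, ...) {
  cat(sprintf("<panel_registry> %d assays, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

require_columns <- function(dt, cols, path) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                    na.strings = NULL, quote = "")
}

#' Read a long-format panel definition table
#'
#' @param path TSV with columns `SEQ_ASSAY_ID`, `Hugo_Symbol`.
#' @return A [panel_registry].
#' @export
read_panels <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, c("SEQ_ASSAY_ID", "Hugo_Symbol"), path)
  panel_registry(split(dt$Hugo_Symbol, dt$SEQ_ASSAY_ID))
}

#' Read a clinical sample table
#'
#' @param path TSV with columns `SAMPLE_ID`, `PATIENT_ID`,
#'   `CANCER_TYPE_DETAILED`, `DEAD`, `SAMPLE_TYPE`, `SEQ_ASSAY_ID`.
#' @param vital_map,sample_type_map Explicit normalization lookups; see
#'   [default_vital_map()].
#' @return data.table with columns `sample_id`, `patient_id`,
#'   `cancer_type_detailed`, `vital_status`, `sample_type`, `assay_id`.
#' @export
read_clinical <- function(path, vital_map = default_vital_map(),
                          sample_type_map = default_sample_type_map()) {
  dt <- read_tsv(path)
  require_columns(dt, c("SAMPLE_ID", "PATIENT_ID", "CANCER_TYPE_DETAILED",
                        "DEAD", "SAMPLE_TYPE", "SEQ_ASSAY_ID"), path)
  if (nrow(dt) == 0L) stop(path, ": clinical table is empty", call. = FALSE)
  cases <- data.table(
    sample_id = dt$SAMPLE_ID,
    patient_id = dt$PATIENT_ID,
    cancer_type_detailed = dt$CANCER_TYPE_DETAILED,
    vital_status = normalize_enum(dt$DEAD, vital_map, VITAL_LEVELS),
    sample_type = normalize_enum(dt$SAMPLE_TYPE, sample_type_map,
                                 SAMPLE_TYPE_LEVELS),
    assay_id = dt$SEQ_ASSAY_ID
  )
  if (anyDuplicated(cases$sample_id))
    stop(path, ": duplicate SAMPLE_ID values", call. = FALSE)
  cases[]
}

#' Read a MAF-like mutation table
#'
#' Variant classification is carried through untouched; every recorded
#' row counts as a mutation unless the caller filters explicitly.
#'
#' @param path TSV with `Hugo_Symbol`, `Tumor_Sample_Barcode`, optional
#'   `Variant_Classification`.
#' @return data.table with `gene`, `sample_id`, `variant_class`.
#' @export
read_mutations <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, c("Hugo_Symbol", "Tumor_Sample_Barcode"), path)
  data.table(
    gene = toupper(trimws(dt$Hugo_Symbol)),
    sample_id = dt$Tumor_Sample_Barcode,
    variant_class = if ("Variant_Classification" %in% names(dt))
      dt$Variant_Classification else NA_character_
  )[nzchar(gene) & nzchar(sample_id)][]
}

#' Read a wide discrete copy-number matrix
#'
#' First column `Hugo_Symbol`, one column per sample; cells are GISTIC-style
#' discrete calls in -2..2 and blank cells mean the (gene, sample) was not
#' profiled.
#'
#' @param path TSV path.
#' @return Long data.table with `gene`, `sample_id`, integer `value`.
#' @export
read_cna <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, "Hugo_Symbol", path)
  long <- data.table::melt(dt, id.vars = "Hugo_Symbol",
                           variable.name = "sample_id", value.name = "value",
                           variable.factor = FALSE)
  long <- long[!is.na(value) & nzchar(trimws(value))]
  v <- suppressWarnings(as.integer(long$value))
  bad <- is.na(v) | !(v %in% -2:2)
  if (any(bad))
    stop(sprintf("%s: %d copy-number cell(s) outside {-2,...,2} (e.g. '%s')",
                 path, sum(bad), long$value[which(bad)[1]]), call. = FALSE)
  data.table(gene = toupper(trimws(long$Hugo_Symbol)),
             sample_id = long$sample_id, value = v)[]
}

#' Read a fusion event table
#' @param path TSV with `Hugo_Symbol`, `Tumor_Sample_Barcode`.
#' @return data.table with `gene`, `sample_id`.
#' @export
read_fusions <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, c("Hugo_Symbol", "Tumor_Sample_Barcode"), path)
  data.table(gene = toupper(trimws(dt$Hugo_Symbol)),
             sample_id = dt$Tumor_Sample_Barcode)[nzchar(gene) & nzchar(sample_id)][]
}

#' Read a Cancer Gene Census style annotation table
#'
#' The `MUTATION_TYPES` column is a comma-separated token list; token `D`
#' (large deletion) permits copy-number loss to count as an alteration,
#' token `A` (amplification) permits gains.
#'
#' @param path TSV with `GENE_SYMBOL`, `MUTATION_TYPES`.
#' @return data.table with `gene`, `allows_deletion`, `allows_amplification`.
#' @export
read_cgc <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, c("GENE_SYMBOL", "MUTATION_TYPES"), path)
  toks <- lapply(strsplit(dt$MUTATION_TYPES, ","), function(x) toupper(trimws(x)))
  out <- data.table(
    gene = toupper(trimws(dt$GENE_SYMBOL)),
    allows_deletion = vapply(toks, function(x) "D" %in% x, logical(1)),
    allows_amplification = vapply(toks, function(x) "A" %in% x, logical(1))
  )
  if (anyDuplicated(out$gene))
    stop(path, ": more than one row for gene(s): ",
         paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "),
         call. = FALSE)
  out[]
}

#' Read a full registry bundle
#'
#' Loads clinical, mutation and panel tables (copy-number and fusion
#' optionally), validates foreign keys, and drops genomic rows that
#' reference samples absent from the clinical table, reporting the count
#' per source on stderr.
#'
#' @param clinical_path,mutation_path,panel_path Required TSV paths.
#' @param cna_path,fusion_path Optional TSV paths.
#' @param vital_map,sample_type_map Passed to [read_clinical()].
#' @return A `comut_registry`: list with `panels`, `cases`, `mutations`,
#'   `cna`, `fusions` and a named integer vector `dropped`.
#' @export
read_registry <- function(clinical_path, mutation_path, panel_path,
                          cna_path = NULL, fusion_path = NULL,
                          vital_map = default_vital_map(),
                          sample_type_map = default_sample_type_map()) {
  panels <- read_panels(panel_path)
  cases <- read_clinical(clinical_path, vital_map, sample_type_map)
  unknown_assay <- setdiff(unique(cases$assay_id), names(panels))
  if (length(unknown_assay))
    stop("clinical table references assay_id(s) absent from the panel table: ",
         paste(unknown_assay, collapse = ", "), call. = FALSE)

  keep <- function(dt, what) {
    bad <- !(dt$sample_id %in% cases$sample_id)
    if (any(bad))
      message(sprintf("%s: dropped %d row(s) referencing unknown sample_ids",
                      what, sum(bad)))
    list(dt = dt[!bad], n = sum(bad))
  }
  mut <- keep(read_mutations(mutation_path), "mutations")
  cna <- if (!is.null(cna_path)) keep(read_cna(cna_path), "cna") else
    list(dt = data.table(gene = character(), sample_id = character(),
                         value = integer()), n = 0L)
  fus <- if (!is.null(fusion_path)) keep(read_fusions(fusion_path), "fusions") else
    list(dt = data.table(gene = character(), sample_id = character()), n = 0L)

  structure(list(panels = panels, cases = cases, mutations = mut$dt,
                 cna = cna$dt, fusions = fus$dt,
                 dropped = c(mutations = mut$n, cna = cna$n, fusions = fus$n)),
            class = "comut_registry")
}

#' @export
print.comut_registry <- function(x, ...) {
  cat(sprintf(paste0("<comut_registry> %d cases, %d cancer types, %d panels, ",
                     "%d mutation rows, %d CNA calls, %d fusions\n"),
              nrow(x$cases), length(unique(x$cases$cancer_type_detailed)),
              length(x$panels), nrow(x$mutations), nrow(x$cna), nrow(x$fusions)))
  invisible(x)
}

#' Write a registry bundle back to its file dialects
#'
#' Inverse of [read_registry()] up to normalization (symbols upper-cased,
#' enums normalized). Used for round-trip checks and for materializing
#' simulated registries.
#'
#' @param registry A `comut_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(clinical = file.path(dir, "clinical.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             panels = file.path(dir, "panels.tsv"))
  cs <- registry$cases
  data.table::fwrite(data.table(
    SAMPLE_ID = cs$sample_id, PATIENT_ID = cs$patient_id,
    CANCER_TYPE_DETAILED = cs$cancer_type_detailed,
    DEAD = c(alive = "False", dead = "True", unknown = "")[cs$vital_status],
    SAMPLE_TYPE = c(primary = "Primary", metastasis = "Metastasis",
                    unknown = "")[cs$sample_type],
    SEQ_ASSAY_ID = cs$assay_id), paths["clinical"], sep = "\t")
  data.table::fwrite(data.table(
    Hugo_Symbol = registry$mutations$gene,
    Tumor_Sample_Barcode = registry$mutations$sample_id,
    Variant_Classification = registry$mutations$variant_class),
    paths["mutations"], sep = "\t")
  pan <- data.table(
    SEQ_ASSAY_ID = rep(names(registry$panels), lengths(registry$panels)),
    Hugo_Symbol = unlist(registry$panels, use.names = FALSE))
  data.table::fwrite(pan, paths["panels"], sep = "\t")
  if (nrow(registry$cna)) {
    wide <- data.table::dcast(registry$cna, gene ~ sample_id, value.var = "value")
    data.table::setnames(wide, "gene", "Hugo_Symbol")
    data.table::fwrite(wide, file.path(dir, "cna.tsv"), sep = "\t")
    paths <- c(paths, cna = file.path(dir, "cna.tsv"))
  }
  if (nrow(registry$fusions)) {
    data.table::fwrite(data.table(
      Hugo_Symbol = registry$fusions$gene,
      Tumor_Sample_Barcode = registry$fusions$sample_id),
      file.path(dir, "fusions.tsv"), sep = "\t")
    paths <- c(paths, fusions = file.path(dir, "fusions.tsv"))
  }
  invisible(paths)
}

#' Cases whose sequencing panel covers both genes of a pair
#'
#' Only cases assayed on platforms covering both genes contribute to a
#' pair's denominator; coverage varies by pair, so so does the case set.
#'
#' @param pair Character vector of two distinct gene symbols.
#' @param panels A [panel_registry].
#' @param cases Clinical case table.
#' @return The covered subset of `cases`, input order preserved.
#' @export
cases_covering <- function(pair, panels, cases) {
  pair <- toupper(pair)
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("pair must be two distinct gene symbols")
  ok <- vapply(panels, function(g) all(pair %in% g), logical(1))
  cases[cases$assay_id %in% names(panels)[ok]]
}

#' Per-gene panel coverage counts
#' @param panels A [panel_registry].
#' @return data.table with `gene` and `n_panels`, one row per gene.
#' @export
panel_coverage <- function(panels) {
  dt <- data.table(gene = unlist(panels, use.names = FALSE),
                   assay = rep(names(panels), lengths(panels)))
  dt[, .(n_panels = data.table::uniqueN(assay)), by = gene][order(gene)]
}

#' Select genes covered by at least a minimum number of panels
#'
#' Restricting the screen to widely covered genes keeps the per-pair
#' denominators large and comparable across pairs.
#'
#' @param panels A [panel_registry].
#' @param min_panels Inclusive threshold (>= 1).
#' @return Lexicographically sorted character vector of gene symbols.
#' @export
select_genes_by_coverage <- function(panels, min_panels) {
  stopifnot(min_panels >= 1)
  cov <- panel_coverage(panels)
  sort(cov[cov$n_panels >= min_panels, gene])
}

#' Enumerate unordered gene pairs
#' @param genes Character vector of >= 2 distinct symbols.
#' @return data.table with `gene1 < gene2` lexicographically, choose(n, 2) rows.
#' @export
enumerate_pairs <- function(genes) {
  genes <- sort(unique(toupper(genes)))
  if (length(genes) < 2L) stop("need at least two genes")
  idx <- utils::combn(length(genes), 2L)
  data.table(gene1 = genes[idx[1, ]], gene2 = genes[idx[2, ]])
}

#' Collapse a registry to one case per patient
#'
#' The analysis unit is the sequenced case; patient-level deduplication is
#' off by default but available (first case per patient in table order).
#'
#' @param cases Clinical case table.
#' @return Case table with the first case per patient.
#' @export
dedupe_patients <- function(cases) {
  cases[!duplicated(cases$patient_id)]
}
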