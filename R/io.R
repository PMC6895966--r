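# On-disk column layout.  Standard MAF columns first, then the evidence
# extension columns needed by the somatic filter cascade; written in this
# fixed order.  Missing numeric cells are empty strings on disk, never 0
# (0 is a meaningful allele frequency).
.maf_columns <- c(
  Hugo_Symbol = "gene", Chromosome = "chromosome",
  Start_Position = "position", Reference_Allele = "ref_allele",
  Tumor_Seq_Allele2 = "alt_allele",
  Variant_Classification = "variant_classification",
  Variant_Type = "variant_type", Tumor_Sample_Barcode = "sample_id",
  t_depth = "tumor_depth", t_alt_count = "tumor_alt_reads",
  t_vaf = "tumor_vaf", n_depth = "normal_depth"
)
.ext_columns <- c(
  phred_quality = "phred_quality", strand_bias_p = "strand_bias_p",
  normal_vaf = "normal_vaf", dbsnp_member = "dbsnp_member",
  pop_af_1kg_eur = "pop_af_1kg_eur", pop_af_exac_nfe = "pop_af_exac_nfe"
)

.numeric_fields <- c("position", "tumor_depth", "tumor_alt_reads",
                     "tumor_vaf", "normal_depth", "phred_quality",
                     "strand_bias_p", "normal_vaf", "pop_af_1kg_eur",
                     "pop_af_exac_nfe")

# Shortest decimal string that reads back to the identical double.
.format_numeric <- function(x) {
  s <- as.character(x)
  ok <- is.na(x)
  chk <- !ok & (suppressWarnings(as.numeric(s)) == x)
  bad <- which(!ok & !chk)
  if (length(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s[is.na(x)] <- ""
  s
}

.parse_numeric <- function(s, column) {
  s[s == ""] <- NA_character_
  v <- suppressWarnings(as.numeric(s))
  bad <- which(!is.na(s) & is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                 s[bad[1]], column, bad[1]))
  v
}

#' Variant identity key
#'
#' Genomic identity of a variant: `chromosome:position:ref>alt`.  Two calls of
#' the same event at the two timepoints share this key; two different
#' mutations in one gene do not.
#'
#' @param variants Variant data frame (see [read_variant_table()]).
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  paste0(variants$chromosome, ":", variants$position, ":",
         variants$ref_allele, ">", variants$alt_allele)
}

#' Validate a variant table
#'
#' Checks the internal invariants of a variant table: alternate reads never
#' exceed depth, reference and alternate alleles differ, the stored VAF (when
#' present) agrees with `tumor_alt_reads / tumor_depth` to within 0.005, and
#' the genomic key is unique within each sample.
#'
#' @param variants Variant data frame.
#' @return `variants`, invisibly, on success; otherwise an error.
#' @export
validate_variants <- function(variants) {
  with(variants, {
    if (any(tumor_alt_reads > tumor_depth, na.rm = TRUE))
      stop("tumor_alt_reads exceeds tumor_depth")
    if (any(ref_allele == alt_allele))
      stop("ref_allele equals alt_allele")
    ok <- !is.na(tumor_vaf) & !is.na(tumor_depth) & tumor_depth > 0
    dev <- abs(tumor_vaf[ok] - tumor_alt_reads[ok] / tumor_depth[ok])
    if (any(dev > 0.005))
      stop("tumor_vaf inconsistent with tumor_alt_reads/tumor_depth")
  })
  key <- paste(variants$sample_id, variant_key(variants))
  if (anyDuplicated(key))
    stop("duplicate variant key within a sample: ", key[anyDuplicated(key)])
  invisible(variants)
}

#' Read a tab-delimited somatic variant table
#'
#' Reads a MAF-compatible variant table into the package's internal layout
#' (one row per variant call per sample).  The `"maf"` dialect expects the
#' standard columns only; the `"extended"` dialect additionally reads the
#' evidence columns required by the somatic filter cascade (`phred_quality`,
#' `strand_bias_p`, `normal_vaf`, `dbsnp_member`, `pop_af_1kg_eur`,
#' `pop_af_exac_nfe`).  Extension columns absent from the file load as
#' missing values.  `tumor_vaf` is computed from `t_alt_count / t_depth` when
#' the file carries no `t_vaf` column.  Patient id and timepoint are
#' recovered from `Tumor_Sample_Barcode` values of the form
#' `<patient>_PRE` / `<patient>_POST`; other barcodes yield `timepoint = NA`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect `"extended"` (default) or `"maf"`.
#' @return A data frame of variants, one row per input row, in input order.
#' @seealso [write_variant_table()] for the inverse operation.
#' @export
read_variant_table <- function(path, dialect = c("extended", "maf")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  required <- setdiff(names(.maf_columns), "t_vaf")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  out <- data.frame(sample_id = raw[["Tumor_Sample_Barcode"]],
                    stringsAsFactors = FALSE)
  tp <- rep(NA_character_, nrow(raw))
  tp[grepl("_PRE$", out$sample_id)] <- "PRE"
  tp[grepl("_POST$", out$sample_id)] <- "POST"
  out$patient_id <- sub("_(PRE|POST)$", "", out$sample_id)
  out$timepoint <- tp
  for (disk in names(.maf_columns)) {
    internal <- .maf_columns[[disk]]
    if (internal == "sample_id") next
    col <- if (disk %in% names(raw)) raw[[disk]] else
      rep(NA_character_, nrow(raw))
    out[[internal]] <- if (internal %in% .numeric_fields)
      .parse_numeric(col, disk) else { col[col == ""] <- NA; col }
  }
  for (disk in names(.ext_columns)) {
    internal <- .ext_columns[[disk]]
    col <- if (dialect == "extended" && disk %in% names(raw)) raw[[disk]] else
      rep(NA_character_, nrow(raw))
    out[[internal]] <- if (internal == "dbsnp_member") {
      col[col == ""] <- NA
      as.logical(col)
    } else .parse_numeric(col, disk)
  }
  no_vaf <- is.na(out$tumor_vaf) & !is.na(out$tumor_depth) & out$tumor_depth > 0
  out$tumor_vaf[no_vaf] <-
    out$tumor_alt_reads[no_vaf] / out$tumor_depth[no_vaf]
  out <- out[, c("patient_id", "sample_id", "timepoint",
                 setdiff(unname(c(.maf_columns, .ext_columns)), "sample_id"))]
  validate_variants(out)
  out
}

#' Write a variant table
#'
#' Writes variants in the fixed on-disk column order (standard MAF columns
#' followed by the evidence extension columns).  Numeric cells are rendered
#' with the shortest decimal representation that reads back bit-exact, and
#' missing values as empty strings, so `read_variant_table(write_variant_table(x))`
#' is the identity on every field including missing-value status.
#'
#' @param variants Variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  cols <- c(.maf_columns, .ext_columns)
  disk <- data.frame(row.names = seq_len(nrow(variants)))
  for (name in names(cols)) {
    v <- variants[[cols[[name]]]]
    disk[[name]] <- if (is.numeric(v)) .format_numeric(v) else {
      s <- as.character(v); s[is.na(s)] <- ""; s
    }
  }
  utils::write.table(disk, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.  Lines with
#' fewer than three fields are a format error (reported with the line
#' number).  Symbols are upper-cased and deduplicated within each set.
#'
#' @param path Path to a GMT file.
#' @param source Source tag recorded for every set in the file: one of
#'   `"C2"`, `"KEGG"`, `"GO"`, `"custom"`.
#' @return A named list of character vectors (class `"gene_sets"`), with a
#'   per-set `source` attribute.
#' @export
read_gene_sets <- function(path, source = c("custom", "C2", "KEGG", "GO")) {
  source <- match.arg(source)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield < 3))
    stop(sprintf("GMT line %d has %d field(s); need at least 3 (name, description, gene)",
                 which(nfield < 3)[1], nfield[nfield < 3][1]))
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(toupper(g)))
  gene_set_collection(sets, source = source)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of HUGO symbols.
#' @param source Source tag, recycled across sets.
#' @return A `"gene_sets"` object.
#' @export
gene_set_collection <- function(sets, source = "custom") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (any(lengths(sets) == 0))
    stop("empty gene set: ", names(sets)[lengths(sets) == 0][1])
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(sets, source = rep_len(source, length(sets)), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets,",
      length(unique(unlist(x))), "distinct genes\n")
  src <- table(attr(x, "source"))
  cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read an undirected protein-protein interaction edge list
#'
#' Reads a two-column tab-delimited file of interacting gene symbol pairs.
#' Self-loops are dropped; duplicate and reversed pairs are collapsed, so the
#' result is invariant under row permutation and pair reversal of the input.
#'
#' @param path Path to a TSV whose first two columns are gene symbols.
#' @return A data frame with columns `gene_a`, `gene_b` (each pair sorted
#'   alphabetically, `gene_a < gene_b`), one row per undirected edge.
#' @export
read_ppi_edges <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) < 2) stop("PPI edge list needs at least two columns")
  make_edge_list(raw[[1]], raw[[2]])
}

#' @rdname read_ppi_edges
#' @param gene_a,gene_b Character vectors of interacting symbol pairs.
#' @export
make_edge_list <- function(gene_a, gene_b) {
  a <- toupper(gene_a); b <- toupper(gene_b)
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  e <- unique(data.frame(gene_a = lo, gene_b = hi,
                         stringsAsFactors = FALSE))
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Read a clinical sample sheet
#'
#' Expected columns: `patient_id`, `age_years`, `response` (`pCR` or `RD`),
#' `relapse` (0/1 or TRUE/FALSE), `stage`, `grade`, `stils_pre`,
#' `stils_post` (stromal tumor-infiltrating lymphocyte percentages, 0-100).
#' Missing optional cells load as `NA`.
#'
#' @param path Path to a tab-delimited clinical sheet.
#' @return A data frame of clinical records, one per patient.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  need <- c("patient_id", "response", "relapse")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required clinical column(s): ", paste(miss, collapse = ", "))
  bad <- !(raw$response %in% c("pCR", "RD", ""))
  if (any(bad))
    stop(sprintf("unknown response label '%s' (allowed: pCR, RD)",
                 raw$response[bad][1]))
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else
    rep(NA_character_, nrow(raw))
  out <- data.frame(
    patient_id = raw$patient_id,
    age_years = .parse_numeric(grab("age_years"), "age_years"),
    response = ifelse(raw$response == "", NA, raw$response),
    relapse = as.logical(.parse_numeric(
      ifelse(raw$relapse %in% c("TRUE", "FALSE"),
             as.character(as.integer(as.logical(raw$relapse))), raw$relapse),
      "relapse")),
    stage = ifelse(grab("stage") == "", NA, grab("stage")),
    grade = ifelse(grab("grade") == "", NA, grab("grade")),
    stils_pre = .parse_numeric(grab("stils_pre"), "stils_pre"),
    stils_post = .parse_numeric(grab("stils_post"), "stils_post"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$response) & is.na(out$relapse)))
    stop("response and relapse are both missing for patient ",
         out$patient_id[is.na(out$response) & is.na(out$relapse)][1])
  out
}

#' Cohort-level clinical arithmetic
#'
#' Counts and percentages summarizing a cohort: pathological complete
#' response (pCR) rate, relapse rate, and — when a variant table is supplied —
#' sequencing evaluability (patients with a usable pre-treatment sample, a
#' post-treatment sample, and both).
#'
#' @param clinical Clinical data frame (see [read_clinical_table()]).
#' @param variants Optional variant data frame; evaluability is derived from
#'   which `patient_id`/`timepoint` combinations carry at least one record.
#' @return A list of counts and percentages (percent scale, unrounded).
#' @export
cohort_summary <- function(clinical, variants = NULL) {
  n <- nrow(clinical)
  out <- list(
    n_patients = n,
    n_pcr = sum(clinical$response == "pCR", na.rm = TRUE),
    n_relapse = sum(clinical$relapse, na.rm = TRUE)
  )
  out$pcr_pct <- 100 * out$n_pcr / n
  out$relapse_pct <- 100 * out$n_relapse / n
  if (!is.null(variants)) {
    pre <- unique(variants$patient_id[variants$timepoint == "PRE"])
    post <- unique(variants$patient_id[variants$timepoint == "POST"])
    out$n_pre_evaluable <- length(pre)
    out$n_post_evaluable <- length(post)
    out$n_paired <- length(intersect(pre, post))
    out$pre_evaluable_pct <- 100 * out$n_pre_evaluable / n
    out$post_evaluable_pct <- 100 * out$n_post_evaluable / n
    out$paired_pct <- 100 * out$n_paired / n
  }
  out
}
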