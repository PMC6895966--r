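#' Filter-cascade thresholds
#'
#' Named constants driving the eight-rule somatic filter.  Defaults follow
#' the FFPE panel-sequencing cascade this package implements: variants are
#' discarded when phred quality < 30 (R1), strand-bias p < 0.01 (R2), fewer
#' than 7 variant-supporting reads (R3), VAF < 5% at depth < 500x (R4),
#' VAF < 10% for a C>T/G>A substitution — the FFPE deamination artifact
#' signature (R5), population allele frequency >= 1% in a European reference
#' panel together with dbSNP membership or a shallow normal (R6), normal
#' depth < 10x (R7), or normal-sample VAF >= 10% (R8, germline evidence).
#'
#' @param phred_min Minimum phred quality (R1 fires below this).
#' @param strand_bias_p_min Minimum strand-bias p-value (R2).
#' @param alt_reads_min Minimum variant-supporting reads (R3).
#' @param low_vaf VAF floor for R4.
#' @param depth_rescue Depth at or above which R4's VAF floor is waived.
#' @param ffpe_vaf VAF below which C>T/G>A substitutions are flagged (R5).
#' @param pop_af_max Population allele frequency at or above which R6 can fire.
#' @param normal_depth_min Minimum normal-sample depth (R6 clause and R7).
#' @param normal_vaf_max Normal-sample VAF at or above which R8 fires.
#' @return A named list of thresholds.
#' @export
filter_thresholds <- function(phred_min = 30, strand_bias_p_min = 0.01,
                              alt_reads_min = 7, low_vaf = 0.05,
                              depth_rescue = 500, ffpe_vaf = 0.10,
                              pop_af_max = 0.01, normal_depth_min = 10,
                              normal_vaf_max = 0.10) {
  as.list(environment())
}

#' Predicted protein impact of a variant classification
#'
#' Maps the controlled classification vocabulary to impact tiers.  HIGH
#' groups the truncating / loss-of-function classes (nonsense, frameshift,
#' splice site, nonstop, translation start site); MODERATE the
#' protein-altering but non-truncating classes (missense, in-frame indels);
#' LOW is silent; everything else is MODIFIER.
#'
#' @param classification Character vector of variant classifications.
#' @param strict If `TRUE`, an unknown label is an error; otherwise it maps
#'   to `"MODIFIER"`.
#' @return Character vector in `{"HIGH","MODERATE","LOW","MODIFIER"}`.
#' @export
classify_impact <- function(classification, strict = FALSE) {
  high <- c("Nonsense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del",
            "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site")
  moderate <- c("Missense_Mutation", "In_Frame_Ins", "In_Frame_Del")
  known <- c(high, moderate, "Silent", "3'UTR", "5'UTR", "Intron", "IGR",
             "RNA", "Targeted_Region", "3'Flank", "5'Flank",
             "Nonstop_Mutation")
  if (strict && any(!classification %in% known))
    stop("unknown variant classification: ",
         classification[!classification %in% known][1])
  out <- rep("MODIFIER", length(classification))
  out[classification %in% moderate] <- "MODERATE"
  out[classification %in% high] <- "HIGH"
  out[classification == "Silent"] <- "LOW"
  out
}

#' Strand-merged single-base substitution class
#'
#' Collapses single-nucleotide substitutions onto the six pyrimidine-centered
#' classes (`C>A/G>T`, `C>G/G>C`, `C>T/G>A`, `T>A/A>T`, `T>C/A>G`,
#' `T>G/A>C`).  Indels and multi-nucleotide variants return `"NOT_SNV"`.
#' `C>T/G>A` is the cytosine-deamination class characteristic of FFPE
#' artifacts.
#'
#' @param ref,alt Character vectors of reference / alternate alleles
#'   (DNA strings; `"-"` marks an allele absent in an indel representation).
#' @return Character vector of class labels.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- grepl("^[ACGT-]+$", ref) & grepl("^[ACGT-]+$", alt)
  if (any(!ok))
    stop("non-ACGT character in allele: ", paste(ref[!ok][1], alt[!ok][1]))
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref != "-" & alt != "-"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r <- ref; a <- alt
  flip <- snv & r %in% c("A", "G")  # represent on the pyrimidine strand
  r[flip] <- comp[r[flip]]; a[flip] <- comp[a[flip]]
  out <- rep("NOT_SNV", length(ref))
  out[snv] <- paste0(r[snv], ">", a[snv], "/", comp[r[snv]], ">", comp[a[snv]])
  out
}

.rule_ids <- paste0("R", 1:8)

# Per-record rule evaluation.  Returns a list of two logical matrices
# (records x rules): `fails` (rule fires) and `evaluated` (all fields the
# rule needs were present).  Missing population AFs count as 0 for R6
# (absence of evidence of commonness), so R6 is only non-evaluable when its
# dbSNP/normal-depth clause is.
.rule_matrix <- function(variants, thresholds, r6_parse) {
  th <- thresholds
  n <- nrow(variants)
  vaf <- variants$tumor_vaf
  subcl <- substitution_class(variants$ref_allele, variants$alt_allele)
  pop_af <- pmax(ifelse(is.na(variants$pop_af_1kg_eur), 0,
                        variants$pop_af_1kg_eur),
                 ifelse(is.na(variants$pop_af_exac_nfe), 0,
                        variants$pop_af_exac_nfe))
  dbsnp <- variants$dbsnp_member
  ndepth <- variants$normal_depth
  common <- pop_af >= th$pop_af_max
  r6_clause <- dbsnp | ndepth < th$normal_depth_min
  fails <- cbind(
    R1 = variants$phred_quality < th$phred_min,
    R2 = variants$strand_bias_p < th$strand_bias_p_min,
    R3 = variants$tumor_alt_reads < th$alt_reads_min,
    R4 = vaf < th$low_vaf & variants$tumor_depth < th$depth_rescue,
    R5 = vaf < th$ffpe_vaf & subcl == "C>T/G>A",
    R6 = if (r6_parse == "af_and_dbsnp_or_lowdepth")
      common & r6_clause
    else  # literal left-to-right reading: dbSNP OR (shallow normal AND common)
      dbsnp | (ndepth < th$normal_depth_min & common),
    R7 = ndepth < th$normal_depth_min,
    R8 = variants$normal_vaf >= th$normal_vaf_max
  )
  # `&`/`|` are three-valued: an AND with one FALSE operand (or an OR with
  # one TRUE) is settled even when the other field is missing, so a rule is
  # NA — skipped — only when the missing field could change its outcome.
  evaluated <- !is.na(fails)
  fails[is.na(fails)] <- FALSE
  stopifnot(nrow(fails) == n)
  list(fails = fails, evaluated = evaluated)
}

#' Evaluate every filter rule on each variant
#'
#' All eight rules are evaluated for every record (no short-circuiting) so
#' the audit trail is complete.  A rule whose required evidence field is
#' missing is skipped and flagged rather than silently passed.
#'
#' @param variants Variant data frame.
#' @param thresholds See [filter_thresholds()].
#' @param r6_parse Reading of the ambiguous population-frequency rule:
#'   `"af_and_dbsnp_or_lowdepth"` (default) fires R6 when the population
#'   allele frequency is common AND (dbSNP member OR shallow normal);
#'   `"dbsnp_or_lowdepth_and_af"` fires on dbSNP membership OR (shallow
#'   normal AND common).
#' @return A data frame with one row per variant: `sample_id`, `key`,
#'   `failed_rules` and `skipped_rules` (comma-separated rule ids), `passed`.
#' @export
evaluate_rules <- function(variants, thresholds = filter_thresholds(),
                           r6_parse = c("af_and_dbsnp_or_lowdepth",
                                        "dbsnp_or_lowdepth_and_af")) {
  r6_parse <- match.arg(r6_parse)
  rm <- .rule_matrix(variants, thresholds, r6_parse)
  collapse <- function(m) apply(m, 1, function(z)
    paste(.rule_ids[z], collapse = ","))
  data.frame(
    sample_id = variants$sample_id,
    key = variant_key(variants),
    failed_rules = collapse(rm$fails),
    skipped_rules = collapse(!rm$evaluated),
    passed = rowSums(rm$fails) == 0,
    stringsAsFactors = FALSE
  )
}

#' Apply the eight-rule somatic filter cascade
#'
#' Splits a variant table into confident somatic calls (no rule fired) and
#' discarded calls, with a full per-variant audit.  In `"lenient"` mode a
#' rule that cannot be evaluated because its evidence field is missing is
#' skipped (and recorded as skipped); in `"strict"` mode any non-evaluable
#' rule discards the variant.
#'
#' @inheritParams evaluate_rules
#' @param mode `"lenient"` (default) or `"strict"` handling of missing
#'   evidence fields.
#' @return An object of class `"filter_result"`: a list with `passed` (the
#'   retained variant rows, input order preserved), `discarded`, and
#'   `outcomes` (the audit data frame from [evaluate_rules()], plus a
#'   `discarded_missing` flag in strict mode).
#' @export
apply_filter_cascade <- function(variants, thresholds = filter_thresholds(),
                                 mode = c("lenient", "strict"),
                                 r6_parse = c("af_and_dbsnp_or_lowdepth",
                                              "dbsnp_or_lowdepth_and_af")) {
  mode <- match.arg(mode)
  r6_parse <- match.arg(r6_parse)
  outcomes <- evaluate_rules(variants, thresholds, r6_parse)
  keep <- outcomes$passed
  if (mode == "strict") {
    outcomes$discarded_missing <- keep & nzchar(outcomes$skipped_rules)
    keep <- keep & !outcomes$discarded_missing
    outcomes$passed <- keep
  }
  structure(
    list(passed = variants[keep, , drop = FALSE],
         discarded = variants[!keep, , drop = FALSE],
         outcomes = outcomes,
         thresholds = thresholds, mode = mode, r6_parse = r6_parse),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  n <- nrow(x$outcomes)
  cat("Somatic filter cascade (", x$mode, " mode): ",
      nrow(x$passed), "/", n, " variants retained\n", sep = "")
  fired <- unlist(strsplit(x$outcomes$failed_rules, ","))
  if (length(fired)) {
    tab <- table(factor(fired, levels = .rule_ids))
    cat("  rule hits:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
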