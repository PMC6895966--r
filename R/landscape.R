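#' Per-sample tumor mutational burden
#'
#' Counts distinct variant keys per sample, both restricted to high/moderate
#' protein impact and over all somatic mutations.  Samples listed in `roster`
#' but absent from the table are retained with count 0.
#'
#' @param variants Filtered variant data frame.
#' @param roster Optional character vector of sample ids fixing the output
#'   rows (zero-count samples included); default: samples present in the
#'   table, in order of first appearance.
#' @return A data frame with columns `sample_id`, `timepoint`,
#'   `n_mutations_high_moderate`, `n_mutations_all`.
#' @export
mutation_burden <- function(variants, roster = NULL) {
  if (is.null(roster)) roster <- unique(variants$sample_id)
  impact <- classify_impact(variants$variant_classification)
  hm <- impact %in% c("HIGH", "MODERATE")
  count_by <- function(keep) {
    tab <- table(factor(variants$sample_id[keep], levels = roster))
    as.integer(tab)
  }
  tp <- variants$timepoint[match(roster, variants$sample_id)]
  tp[is.na(tp)] <- ifelse(grepl("_POST$", roster[is.na(tp)]), "POST",
                          ifelse(grepl("_PRE$", roster[is.na(tp)]), "PRE",
                                 NA))
  data.frame(
    sample_id = roster, timepoint = tp,
    n_mutations_high_moderate = count_by(hm),
    n_mutations_all = count_by(rep(TRUE, nrow(variants))),
    stringsAsFactors = FALSE
  )
}

#' Top recurrently mutated genes as a binary gene-by-sample matrix
#'
#' Ranks genes by the number of samples harboring at least one high/moderate
#' impact mutation, breaking ties alphabetically, and returns the binary
#' presence matrix for the top `top_n` genes (an "oncoplot" matrix).  A gene
#' mutated at several positions in one sample counts once.
#'
#' @param variants Filtered variant data frame.
#' @param top_n Number of genes to keep (default 10).
#' @param roster Optional sample roster fixing/ordering the columns (e.g.
#'   ordered by response group).
#' @return An integer matrix (genes x samples, entries 0/1) of class
#'   `"onco_matrix"`, rows in non-increasing frequency order.
#' @export
recurrent_genes <- function(variants, top_n = 10, roster = NULL) {
  stopifnot(top_n >= 1)
  if (is.null(roster)) roster <- unique(variants$sample_id)
  impact <- classify_impact(variants$variant_classification)
  v <- variants[impact %in% c("HIGH", "MODERATE") &
                  variants$sample_id %in% roster, , drop = FALSE]
  hits <- unique(v[, c("gene", "sample_id")])
  freq <- table(hits$gene)
  ord <- order(-as.integer(freq), names(freq))
  genes <- names(freq)[ord][seq_len(min(top_n, length(freq)))]
  m <- matrix(0L, nrow = length(genes), ncol = length(roster),
              dimnames = list(genes, roster))
  hit <- hits[hits$gene %in% genes, , drop = FALSE]
  m[cbind(hit$gene, hit$sample_id)] <- 1L
  structure(m, class = c("onco_matrix", class(m)))
}

#' Mutation-type and substitution-spectrum summary
#'
#' Tabulates mutation types (`missense`, `truncating` — nonsense, frameshift,
#' nonstop —, `splice`, `in_frame_indel`, `other`) and, over single-base
#' substitutions only, the six strand-merged substitution classes.
#'
#' @param variants Filtered variant data frame.
#' @return A list with `type_counts` and `substitution_counts` (named
#'   integer vectors; substitution counts sum to the number of SNV records).
#' @export
spectrum_summary <- function(variants) {
  cls <- variants$variant_classification
  type <- rep("other", length(cls))
  type[cls == "Missense_Mutation"] <- "missense"
  type[cls %in% c("Nonsense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del",
                  "Nonstop_Mutation")] <- "truncating"
  type[cls == "Splice_Site"] <- "splice"
  type[cls %in% c("In_Frame_Ins", "In_Frame_Del")] <- "in_frame_indel"
  type_counts <- table(factor(type, levels = c("missense", "truncating",
                                               "splice", "in_frame_indel",
                                               "other")))
  sub <- substitution_class(variants$ref_allele, variants$alt_allele)
  sub_levels <- c("C>A/G>T", "C>G/G>C", "C>T/G>A",
                  "T>A/A>T", "T>C/A>G", "T>G/A>C")
  substitution_counts <- table(factor(sub[sub != "NOT_SNV"],
                                      levels = sub_levels))
  list(type_counts = c(type_counts), substitution_counts = c(substitution_counts))
}

#' Compare mutational burden between two sample groups
#'
#' Wilcoxon rank-sum test on per-sample mutation counts between exactly two
#' groups, with per-group medians and ranges.
#'
#' @param burden A burden table from [mutation_burden()].
#' @param groups Named vector or factor mapping `sample_id` to a group label
#'   (exactly two distinct labels among the burden's samples).
#' @param scope `"high_moderate"` (default) or `"all"`: which count column
#'   to compare.
#' @return A list of class `"burden_comparison"` with the test result and
#'   per-group summaries.
#' @export
compare_burden <- function(burden, groups,
                           scope = c("high_moderate", "all")) {
  scope <- match.arg(scope)
  g <- groups[burden$sample_id]
  if (anyNA(g)) {
    burden <- burden[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2)
    stop("compare_burden requires exactly two groups, got ", length(lev))
  counts <- if (scope == "high_moderate") burden$n_mutations_high_moderate
  else burden$n_mutations_all
  x <- counts[g == lev[1]]; y <- counts[g == lev[2]]
  summarize <- function(v) c(n = length(v), median = stats::median(v),
                             min = min(v), max = max(v))
  structure(
    list(test = wilcoxon_rank_sum(x, y), scope = scope,
         groups = stats::setNames(list(summarize(x), summarize(y)), lev)),
    class = "burden_comparison"
  )
}

#' @export
print.burden_comparison <- function(x, ...) {
  cat("Mutational burden comparison (", x$scope, " scope)\n", sep = "")
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("  %s: n=%d, median %s (range %s-%s)\n", g, s[["n"]],
                format(s[["median"]]), format(s[["min"]]),
                format(s[["max"]])))
  }
  cat("  Wilcoxon rank-sum p =", format.pval(x$test$p_value, digits = 4),
      "\n")
  invisible(x)
}
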