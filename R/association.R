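#' Binary gene-by-sample mutation status matrix
#'
#' Entry is 1 when the sample carries at least one high/moderate-impact
#' mutation of the gene (mutation count is deliberately collapsed to
#' presence/absence), 0 otherwise.
#'
#' @param variants Filtered variant data frame.
#' @param samples Character vector of sample ids defining the columns
#'   (samples without mutations yield all-zero columns).
#' @param impact Character vector of impact tiers that count as mutated
#'   (default high/moderate).
#' @return An integer 0/1 matrix, genes x samples, with attribute
#'   `scope = "gene"`.
#' @export
binarize_mutations <- function(variants, samples = NULL,
                               impact = c("HIGH", "MODERATE")) {
  if (is.null(samples)) samples <- unique(variants$sample_id)
  if (length(samples) == 0) stop("no samples supplied")
  v <- variants[classify_impact(variants$variant_classification) %in% impact &
                  variants$sample_id %in% samples, , drop = FALSE]
  genes <- sort(unique(v$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  hit <- unique(v[, c("gene", "sample_id")])
  if (nrow(hit)) m[cbind(hit$gene, hit$sample_id)] <- 1L
  attr(m, "scope") <- "gene"
  m
}

#' Pathway-level mutation status
#'
#' A pathway is mutated in a sample when at least one of its member genes is
#' mutated there (logical OR over the gene matrix rows).  Gene sets with no
#' member present in the matrix are dropped; the number dropped is recorded
#' in the `n_dropped` attribute and reported as a message.
#'
#' @param gene_matrix Binary gene x sample matrix from
#'   [binarize_mutations()].
#' @param gene_sets A [gene_set_collection()].
#' @return An integer 0/1 matrix, pathways x samples, with attribute
#'   `scope = "pathway"`.
#' @export
pathway_status <- function(gene_matrix, gene_sets) {
  if (length(gene_sets) == 0) stop("empty gene-set collection")
  present <- lapply(gene_sets, intersect, rownames(gene_matrix))
  keep <- lengths(present) > 0
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " gene set(s) with no gene in the matrix dropped")
  rows <- lapply(present[keep], function(g)
    as.integer(colSums(gene_matrix[g, , drop = FALSE]) > 0))
  m <- do.call(rbind, rows)
  if (is.null(m))
    m <- matrix(0L, nrow = 0, ncol = ncol(gene_matrix))
  dimnames(m) <- list(names(present)[keep], colnames(gene_matrix))
  attr(m, "scope") <- "pathway"
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Associate binary mutation status with treatment response
#'
#' One two-sided Fisher's exact test per feature (gene or pathway) on the
#' 2x2 table of mutation status (mutated / wild-type) against response
#' (pCR / RD), with Benjamini-Hochberg correction across all features of the
#' matrix.  Features mutated in none or all samples carry no information for
#' a 2x2 association; they are reported with `p = 1` and flagged.
#'
#' @param matrix Binary feature x sample matrix ([binarize_mutations()] or
#'   [pathway_status()]).
#' @param labels Named character vector mapping sample id to `"pCR"` or
#'   `"RD"`; every matrix column must be covered and both classes present.
#' @return A data frame, one row per feature: counts `mut_pcr`, `mut_rd`,
#'   `wt_pcr`, `wt_rd`, `odds_ratio`, `p_value`, `q_value`, `informative`,
#'   sorted by p-value.
#' @export
feature_response_association <- function(matrix, labels) {
  lab <- labels[colnames(matrix)]
  if (anyNA(lab))
    stop("missing response label for sample(s): ",
         paste(colnames(matrix)[is.na(lab)], collapse = ", "))
  if (!all(lab %in% c("pCR", "RD")))
    stop("response labels must be 'pCR' or 'RD'")
  if (length(unique(lab)) < 2)
    stop("both response classes must be present")
  is_pcr <- lab == "pCR"
  res <- lapply(rownames(matrix), function(f) {
    mut <- matrix[f, ] == 1
    a <- sum(mut & is_pcr); b <- sum(mut & !is_pcr)
    cc <- sum(!mut & is_pcr); d <- sum(!mut & !is_pcr)
    informative <- (a + b) > 0 && (cc + d) > 0
    ft <- if (informative) fisher_exact_2x2(a, b, cc, d) else
      list(p_value = 1, odds_ratio = NA_real_)
    data.frame(feature = f, mut_pcr = a, mut_rd = b, wt_pcr = cc, wt_rd = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               informative = informative, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scope") <- attr(matrix, "scope")
  out
}

#' Select pathways preferentially mutated in non-responders
#'
#' Reporting filter for pathway matrices: keeps pathways mutated in at least
#' `min_rd_count` residual-disease samples and at most `max_pcr_count` pCR
#' samples.
#'
#' @inheritParams feature_response_association
#' @param min_rd_count Minimum number of mutated RD samples (default 3).
#' @param max_pcr_count Maximum number of mutated pCR samples (default 0).
#' @return Character vector of pathway names meeting the rule.
#' @export
rd_enriched_pathways <- function(matrix, labels, min_rd_count = 3,
                                 max_pcr_count = 0) {
  lab <- labels[colnames(matrix)]
  rd_hits <- rowSums(matrix[, lab == "RD", drop = FALSE])
  pcr_hits <- rowSums(matrix[, lab == "pCR", drop = FALSE])
  rownames(matrix)[rd_hits >= min_rd_count & pcr_hits <= max_pcr_count]
}
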