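#' Pairwise mutation co-occurrence / mutual exclusivity scan
#'
#' Tests every unordered pair of eligible genes (each mutated in at least
#' `min_mutated_samples` samples) for association of their binary mutation
#' profiles with a two-sided Fisher's exact test, then applies
#' Benjamini-Hochberg correction across all tested pairs.  A pair whose
#' odds ratio exceeds 1 co-occurs; otherwise it trends toward mutual
#' exclusivity.
#'
#' @param matrix Binary gene x sample matrix over at least 3 samples.
#' @param min_mutated_samples Eligibility floor per gene (default 2).
#' @return A data frame, one row per tested pair: `gene_a`, `gene_b`
#'   (alphabetical), counts `both`, `a_only`, `b_only`, `neither`,
#'   `odds_ratio`, `p_value`, `q_value`, `direction`, ordered by p-value.
#' @export
cooccurrence_scan <- function(matrix, min_mutated_samples = 2) {
  if (ncol(matrix) < 3)
    stop("co-occurrence scan requires at least 3 samples")
  eligible <- rownames(matrix)[rowSums(matrix) >= min_mutated_samples]
  eligible <- sort(eligible)
  if (length(eligible) < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      both = integer(), a_only = integer(),
                      b_only = integer(), neither = integer(),
                      odds_ratio = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  m <- matrix[eligible, , drop = FALSE]
  idx <- utils::combn(length(eligible), 2)
  i <- idx[1, ]; j <- idx[2, ]
  # all pair tables at once via cross-products
  both_mat <- tcrossprod(m)
  row_hits <- rowSums(m)
  both <- both_mat[cbind(i, j)]
  a_only <- row_hits[i] - both
  b_only <- row_hits[j] - both
  neither <- ncol(m) - both - a_only - b_only
  # identical tables share one exact test
  key <- paste(both, a_only, b_only, neither)
  uniq <- !duplicated(key)
  stats_by_key <- lapply(which(uniq), function(r)
    fisher_exact_2x2(both[r], a_only[r], b_only[r], neither[r]))
  names(stats_by_key) <- key[uniq]
  out <- data.frame(
    gene_a = eligible[i], gene_b = eligible[j],
    both = as.integer(both), a_only = as.integer(a_only),
    b_only = as.integer(b_only), neither = as.integer(neither),
    odds_ratio = vapply(stats_by_key[key], `[[`, numeric(1), "odds_ratio"),
    p_value = vapply(stats_by_key[key], `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$q_value <- bh_fdr(out$p_value)
  out$direction <- ifelse(!is.na(out$odds_ratio) & out$odds_ratio > 1,
                          "co_occurrence", "mutual_exclusivity")
  out <- out[order(out$p_value, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significantly co-occurring pairs
#'
#' Convenience gate over [cooccurrence_scan()] output: co-occurring pairs at
#' FDR below `q_max` (the default gate), or at raw p below `p_max` when
#' `p_max` is supplied instead.
#'
#' @param pairs Result of [cooccurrence_scan()].
#' @param q_max FDR threshold (default 0.05).
#' @param p_max Optional raw p-value threshold overriding the FDR gate.
#' @return The significant co-occurring subset of `pairs`.
#' @export
significant_cooccurrence <- function(pairs, q_max = 0.05, p_max = NULL) {
  keep <- pairs$direction == "co_occurrence" &
    (if (is.null(p_max)) pairs$q_value < q_max else pairs$p_value < p_max)
  pairs[keep, , drop = FALSE]
}

#' First-neighbor interaction module around seed genes
#'
#' Expands seed genes to their first neighbors in a protein-protein
#' interaction edge list and restricts the edges to the resulting node set.
#' Seeds absent from the edge list remain as isolated nodes.  Connected
#' components are labelled (component 1 is the largest).
#'
#' @param seed_genes Character vector of seed gene symbols.
#' @param edges Edge list data frame (`gene_a`, `gene_b`) from
#'   [read_ppi_edges()] / [make_edge_list()].
#' @return A list of class `"network_module"`: `nodes` (data frame: `gene`,
#'   `is_seed`, `component`), `edges`, `n_components`.
#' @export
extract_module <- function(seed_genes, edges) {
  if (length(seed_genes) == 0) stop("seed gene set is empty")
  seeds <- unique(toupper(seed_genes))
  touches <- edges$gene_a %in% seeds | edges$gene_b %in% seeds
  neighbors <- setdiff(unique(c(edges$gene_a[touches],
                                edges$gene_b[touches])), seeds)
  nodes <- c(seeds, neighbors)
  sub <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, ,
               drop = FALSE]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  # component ids ordered by decreasing size, ties by smallest member name
  sizes <- comp$csize
  first <- vapply(seq_along(sizes), function(i)
    min(names(comp$membership)[comp$membership == i]), character(1))
  ord <- order(-sizes, first)
  membership <- match(comp$membership, ord)
  nodes_df <- data.frame(gene = nodes, is_seed = nodes %in% seeds,
                         component = membership[match(nodes,
                                                      names(comp$membership))],
                         stringsAsFactors = FALSE)
  nodes_df <- nodes_df[order(nodes_df$component, -nodes_df$is_seed,
                             nodes_df$gene), , drop = FALSE]
  rownames(nodes_df) <- NULL
  rownames(sub) <- NULL
  structure(list(nodes = nodes_df, edges = sub,
                 n_components = as.integer(comp$no)),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat("Interaction module:", nrow(x$nodes), "nodes (",
      sum(x$nodes$is_seed), "seeds ),", nrow(x$edges), "edges,",
      x$n_components, "component(s)\n")
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests the overlap with the query against the
#' hypergeometric upper tail on the given universe; q-values are computed
#' within each source tag (KEGG pathways and GO terms are corrected
#' separately, mirroring their different conventional FDR gates).  Default
#' significance gates: q < 0.05 for KEGG/C2/custom sets, q < 0.01 for GO.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param gene_sets A [gene_set_collection()].
#' @param universe Character vector of background genes; the query is
#'   intersected with it, and so is each set.
#' @param q_max Named or scalar FDR gate(s); scalar applies to all sources,
#'   a named vector (e.g. `c(KEGG = 0.05, GO = 0.01)`) per source.
#' @param significant_only Keep only terms passing their source's gate
#'   (default `TRUE`).
#' @return A data frame: `term`, `source`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `q_value`, ordered by
#'   p-value.  Overlapping genes are in the `genes` column
#'   (comma-separated).
#' @export
enrich_gene_sets <- function(query_genes, gene_sets, universe,
                             q_max = c(C2 = 0.05, KEGG = 0.05, GO = 0.01,
                                       custom = 0.05),
                             significant_only = TRUE) {
  universe <- unique(toupper(universe))
  query <- intersect(unique(toupper(query_genes)), universe)
  if (length(query) == 0)
    stop("query has no genes in the universe")
  N <- length(universe); n <- length(query)
  src <- attr(gene_sets, "source")
  if (is.null(src)) src <- rep("custom", length(gene_sets))
  rows <- lapply(seq_along(gene_sets), function(i) {
    set <- intersect(gene_sets[[i]], universe)
    ov <- intersect(query, set)
    data.frame(term = names(gene_sets)[i], source = src[i],
               overlap = length(ov), set_size = length(set),
               query_size = n, universe_size = N,
               p_value = if (length(set) == 0) 1 else
                 hypergeometric_upper_tail(length(ov), length(set), n, N),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$overlap > 0, , drop = FALSE]
  if (nrow(out) == 0) {
    out$q_value <- numeric(0)
    return(out)
  }
  out$q_value <- NA_real_
  for (s in unique(out$source))
    out$q_value[out$source == s] <- bh_fdr(out$p_value[out$source == s])
  if (significant_only) {
    gate <- if (length(q_max) == 1 && is.null(names(q_max)))
      rep(q_max, nrow(out))
    else {
      g <- unname(q_max[out$source])
      g[is.na(g)] <- 0.05
      g
    }
    out <- out[out$q_value < gate, , drop = FALSE]
  }
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
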