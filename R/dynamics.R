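#' Assemble a patient's paired pre/post variant-allele-frequency matrix
#'
#' Collects one patient's PRE and POST variant calls, keyed by genomic
#' identity (chromosome, position, ref, alt — never by gene symbol, so two
#' different mutations of one gene are not conflated).  A mutation absent at
#' a timepoint enters the matrix with VAF 0 rather than being dropped: loss
#' and emergence are the signal of interest.
#'
#' @param variants Filtered variant data frame containing the patient's
#'   samples.
#' @param patient_id Patient identifier.
#' @return A list of class `"paired_patient"`: `patient_id`, `keys`,
#'   `genes`, and `vaf` (a keys x `c("PRE","POST")` matrix), rows in
#'   lexicographic key order.
#' @export
paired_patient <- function(variants, patient_id) {
  v <- variants[variants$patient_id == patient_id, , drop = FALSE]
  pre <- v[v$timepoint == "PRE", , drop = FALSE]
  post <- v[v$timepoint == "POST", , drop = FALSE]
  pre_keys <- variant_key(pre); post_keys <- variant_key(post)
  keys <- sort(unique(c(pre_keys, post_keys)))
  if (length(keys) == 0)
    stop("no variants for patient ", patient_id)
  vaf <- matrix(0, nrow = length(keys), ncol = 2,
                dimnames = list(keys, c("PRE", "POST")))
  vaf[pre_keys, "PRE"] <- pre$tumor_vaf
  vaf[post_keys, "POST"] <- post$tumor_vaf
  genes <- character(length(keys))
  genes[match(post_keys, keys)] <- post$gene
  genes[match(pre_keys, keys)] <- pre$gene
  structure(list(patient_id = patient_id, keys = keys, genes = genes,
                 vaf = vaf),
            class = "paired_patient")
}

#' Partition variant keys into shared and private sets
#'
#' @param pre_keys,post_keys Character vectors of variant keys observed at
#'   each timepoint.
#' @return A list with `shared`, `private_pre`, `private_post` (a set
#'   partition of the key union).
#' @export
partition_shared_private <- function(pre_keys, post_keys) {
  pre_keys <- unique(pre_keys); post_keys <- unique(post_keys)
  list(shared = intersect(pre_keys, post_keys),
       private_pre = setdiff(pre_keys, post_keys),
       private_post = setdiff(post_keys, pre_keys))
}

#' Fate of a VAF cluster between timepoints
#'
#' A cluster is `lost` when every member's post-treatment VAF falls below the
#' detection threshold while at least one member was detectable
#' pre-treatment; `emergent` in the mirror case; `retained` otherwise.
#'
#' @param pre_vaf,post_vaf Member VAFs at each timepoint.
#' @param detection_threshold VAF below which a mutation counts as absent
#'   (default 0.05, mirroring the filter cascade's VAF floor).
#' @return `"lost"`, `"emergent"`, or `"retained"`.
#' @export
classify_cluster_fate <- function(pre_vaf, post_vaf,
                                  detection_threshold = 0.05) {
  stopifnot(length(pre_vaf) == length(post_vaf), length(pre_vaf) >= 1)
  if (all(post_vaf < detection_threshold) &&
      any(pre_vaf >= detection_threshold)) "lost"
  else if (all(pre_vaf < detection_threshold) &&
           any(post_vaf >= detection_threshold)) "emergent"
  else "retained"
}

#' Stable-vs-changed mutational profile call
#'
#' A patient's profile is `changed` when at least one VAF cluster was lost
#' or emerged between timepoints, `stable` when every cluster was retained.
#'
#' @param fates Character vector of cluster fates.
#' @return `"stable"` or `"changed"`.
#' @export
classify_patient_profile <- function(fates) {
  stopifnot(length(fates) >= 1)
  if (any(fates %in% c("lost", "emergent"))) "changed" else "stable"
}

#' Cluster a patient's mutations by paired VAF
#'
#' Agglomerative hierarchical clustering (Ward minimum-variance linkage on
#' Euclidean distances) of the patient's mutations as points in the
#' (pre-VAF, post-VAF) plane.  The number of clusters is chosen to maximize
#' the mean silhouette width over `k = 2..min(k_max, n - 1)`; when fewer
#' than 4 mutations are available or the best silhouette falls below
#' `silhouette_min`, a single cluster is used.  Rows are processed in
#' lexicographic key order so the result is deterministic.  Clusters are
#' labelled C1..Ck by decreasing mean pre-treatment VAF.
#'
#' @param paired A [paired_patient()] object.
#' @param k_max Largest number of clusters considered (default 6).
#' @param silhouette_min Minimum mean silhouette to accept a multi-cluster
#'   solution (default 0.25).
#' @param detection_threshold Passed to [classify_cluster_fate()].
#' @param small_n_profile Profile rule when only a single cluster is
#'   resolved (`k = 1`): `"mutation"` (default) falls back to per-mutation
#'   fates — a patient whose lone cluster is retained is still called
#'   `changed` when an individual mutation was clearly lost or emerged —
#'   while `"cluster"` uses the single cluster's fate alone.  The mutation
#'   fallback matches how single-mutation patients are judged in practice
#'   (a unique mutation present at both timepoints is a stable profile; one
#'   that vanished is not).
#' @return An object of class `"vaf_clusters"`: a list with `patient_id`,
#'   `assignments` (data frame: key, gene, pre_vaf, post_vaf, cluster),
#'   `clusters` (per-cluster size, mean VAFs, fate), `k`, `silhouette`,
#'   and `profile`.
#' @export
cluster_vafs <- function(paired, k_max = 6, silhouette_min = 0.25,
                         detection_threshold = 0.05,
                         small_n_profile = c("mutation", "cluster")) {
  small_n_profile <- match.arg(small_n_profile)
  stopifnot(inherits(paired, "paired_patient"))
  x <- paired$vaf[order(rownames(paired$vaf)), , drop = FALSE]
  genes <- paired$genes[order(paired$keys)]
  n <- nrow(x)
  sil <- NA_real_
  if (n < 4) {
    labels <- rep(1L, n)
    k <- 1L
  } else {
    d <- stats::dist(x)
    hc <- stats::hclust(d, method = "ward.D2")
    ks <- seq(2L, min(k_max, n - 1L))
    mean_sil <- vapply(ks, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"])
    }, numeric(1))
    best <- which.max(mean_sil)  # ties resolve to the smallest k
    if (mean_sil[best] < silhouette_min) {
      labels <- rep(1L, n); k <- 1L
    } else {
      labels <- stats::cutree(hc, ks[best]); k <- ks[best]
      sil <- mean_sil[best]
    }
  }
  # relabel C1..Ck by decreasing mean pre-VAF (then post-VAF, then key)
  means <- vapply(seq_len(k), function(cl)
    c(mean(x[labels == cl, "PRE"]), mean(x[labels == cl, "POST"])),
    numeric(2))
  first_key <- vapply(seq_len(k), function(cl)
    rownames(x)[labels == cl][1], character(1))
  ord <- order(-means[1, ], -means[2, ], first_key)
  relabel <- match(labels, ord)
  clusters <- data.frame(
    cluster = paste0("C", seq_len(k)),
    n_mutations = as.integer(table(factor(relabel, levels = seq_len(k)))),
    mean_pre_vaf = means[1, ord], mean_post_vaf = means[2, ord],
    fate = vapply(seq_len(k), function(i) {
      memb <- relabel == i
      classify_cluster_fate(x[memb, "PRE"], x[memb, "POST"],
                            detection_threshold)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  profile_fates <- clusters$fate
  if (k == 1 && small_n_profile == "mutation")
    profile_fates <- vapply(seq_len(n), function(i)
      classify_cluster_fate(x[i, "PRE"], x[i, "POST"], detection_threshold),
      character(1))
  structure(
    list(patient_id = paired$patient_id,
         assignments = data.frame(
           key = rownames(x), gene = genes,
           pre_vaf = x[, "PRE"], post_vaf = x[, "POST"],
           cluster = paste0("C", relabel), stringsAsFactors = FALSE,
           row.names = NULL),
         clusters = clusters, k = k, silhouette = sil,
         profile = classify_patient_profile(profile_fates),
         detection_threshold = detection_threshold),
    class = "vaf_clusters"
  )
}

#' @export
print.vaf_clusters <- function(x, ...) {
  cat("Paired VAF clustering for patient", x$patient_id, "\n")
  cat("  ", nrow(x$assignments), " mutations in ", x$k, " cluster(s)",
      if (!is.na(x$silhouette))
        sprintf(" (mean silhouette %.2f)", x$silhouette), "\n", sep = "")
  print(x$clusters, row.names = FALSE)
  cat("  profile:", x$profile, "\n")
  invisible(x)
}

#' @export
plot.vaf_clusters <- function(x, ...) {
  a <- x$assignments
  cols <- seq_len(x$k) + 1
  graphics::plot(a$pre_vaf, a$post_vaf,
                 col = cols[as.integer(sub("^C", "", a$cluster))],
                 pch = 19, xlim = c(0, max(a$pre_vaf, 0.5)),
                 ylim = c(0, max(a$post_vaf, 0.5)),
                 xlab = "pre-treatment VAF", ylab = "post-treatment VAF",
                 main = paste("Patient", x$patient_id, "-", x$profile), ...)
  graphics::abline(h = x$detection_threshold, v = x$detection_threshold,
                   lty = 3, col = "grey50")
  graphics::legend("topright", legend = x$clusters$cluster, col = cols,
                   pch = 19, bty = "n")
  invisible(x)
}

#' Relapse cross-tabulation of mutational profiles
#'
#' 2x2 table of stable/changed profile against relapse, with a two-sided
#' Fisher's exact test.  Patients lacking a relapse label are listed and
#' excluded.
#'
#' @param profiles Data frame with columns `patient_id` and `profile`
#'   (`"stable"`/`"changed"`).
#' @param clinical Clinical data frame with `patient_id` and `relapse`.
#' @return A list with `table` (2x2 matrix: rows stable/changed, columns
#'   relapse/no_relapse), `test`, and `excluded` patient ids.
#' @export
relapse_crosstab <- function(profiles, clinical) {
  if (nrow(profiles) == 0) stop("no profiles supplied")
  relapse <- clinical$relapse[match(profiles$patient_id,
                                    clinical$patient_id)]
  excluded <- profiles$patient_id[is.na(relapse)]
  keep <- !is.na(relapse)
  if (!any(keep)) stop("no patients with relapse labels")
  prof <- factor(profiles$profile[keep], levels = c("stable", "changed"))
  rel <- factor(ifelse(relapse[keep], "relapse", "no_relapse"),
                levels = c("relapse", "no_relapse"))
  tab <- table(prof, rel)
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("stable", "changed"),
                              c("relapse", "no_relapse")))
  list(table = m, test = fisher_exact_2x2(m), excluded = excluded)
}

#' Gene-set enrichment of residual (post-treatment) cluster genes
#'
#' For each VAF cluster, the member genes still mutated after treatment
#' (post VAF at or above the detection threshold) are tested for gene-set
#' enrichment.  Clusters with no post-treatment gene are reported as
#' not-applicable.
#'
#' @param vc A [cluster_vafs()] result.
#' @param gene_sets A [gene_set_collection()].
#' @param universe Character vector of background genes.
#' @param q_max Significance threshold on the BH q-value (default 0.05).
#' @return A data frame: cluster, number of post-mutated genes, enriched
#'   terms (`NA` when not applicable, empty string when none enriched).
#' @export
residual_cluster_pathways <- function(vc, gene_sets, universe,
                                      q_max = 0.05) {
  a <- vc$assignments
  out <- lapply(vc$clusters$cluster, function(cl) {
    genes <- unique(a$gene[a$cluster == cl &
                             a$post_vaf >= vc$detection_threshold])
    if (length(genes) == 0)
      return(data.frame(cluster = cl, n_post_genes = 0L,
                        enriched_terms = NA_character_,
                        stringsAsFactors = FALSE))
    enr <- enrich_gene_sets(genes, gene_sets, universe,
                            q_max = q_max, significant_only = TRUE)
    data.frame(cluster = cl, n_post_genes = length(genes),
               enriched_terms = paste(enr$term, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort-level clonal dynamics analysis
#'
#' Runs the full paired analysis for every patient with both a PRE and a
#' POST sample: shared/private mutation accounting, Ward/Euclidean VAF
#' clustering with silhouette model selection, cluster fates, stable-vs-
#' changed profile calls, and (when clinical data are supplied) the
#' profile-by-relapse cross-tabulation.
#'
#' @param variants Filtered variant data frame.
#' @param clinical Optional clinical data frame (for relapse labels).
#' @param ... Passed to [cluster_vafs()].
#' @return An object of class `"clonal_dynamics"`: list with `patients`
#'   (named list of `vaf_clusters`), `profiles`, `shared_private` (per-
#'   patient counts), and `crosstab` (or `NULL`).
#' @export
clonal_dynamics <- function(variants, clinical = NULL, ...) {
  by_patient <- split(variants$timepoint, variants$patient_id)
  paired_ids <- names(by_patient)[vapply(by_patient, function(tp)
    all(c("PRE", "POST") %in% tp), logical(1))]
  if (length(paired_ids) == 0) stop("no patients with paired samples")
  patients <- lapply(paired_ids, function(p)
    cluster_vafs(paired_patient(variants, p), ...))
  names(patients) <- paired_ids
  profiles <- data.frame(
    patient_id = paired_ids,
    k = vapply(patients, `[[`, integer(1), "k"),
    profile = vapply(patients, `[[`, character(1), "profile"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  sp <- lapply(paired_ids, function(p) {
    v <- variants[variants$patient_id == p, , drop = FALSE]
    parts <- partition_shared_private(
      variant_key(v[v$timepoint == "PRE", , drop = FALSE]),
      variant_key(v[v$timepoint == "POST", , drop = FALSE]))
    data.frame(patient_id = p, n_shared = length(parts$shared),
               n_private_pre = length(parts$private_pre),
               n_private_post = length(parts$private_post),
               stringsAsFactors = FALSE)
  })
  crosstab <- if (!is.null(clinical))
    relapse_crosstab(profiles, clinical) else NULL
  structure(list(patients = patients, profiles = profiles,
                 shared_private = do.call(rbind, sp), crosstab = crosstab),
            class = "clonal_dynamics")
}

#' @export
print.clonal_dynamics <- function(x, ...) {
  n <- nrow(x$profiles)
  n_changed <- sum(x$profiles$profile == "changed")
  cat("Clonal dynamics over", n, "paired patients:",
      n_changed, "changed,", n - n_changed, "stable\n")
  sp <- x$shared_private
  cat(sprintf("  median private pre %s, private post %s, shared %s\n",
              format(stats::median(sp$n_private_pre)),
              format(stats::median(sp$n_private_post)),
              format(stats::median(sp$n_shared))))
  if (!is.null(x$crosstab)) {
    cat("  profile x relapse:\n")
    print(x$crosstab$table)
    cat("  Fisher p =", format.pval(x$crosstab$test$p_value, digits = 4),
        "\n")
  }
  invisible(x)
}

#' @export
summary.clonal_dynamics <- function(object, ...) {
  print(object)
  for (p in object$patients) print(p)
  invisible(object)
}
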