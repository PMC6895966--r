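paired_from_points <- function(pre, post, patient = "pX") {
  n <- length(pre)
  keys <- sprintf("1:%03d:A>G", seq_len(n))
  vaf <- cbind(PRE = pre, POST = post)
  rownames(vaf) <- keys
  structure(list(patient_id = patient, keys = keys,
                 genes = sprintf("GENE%02d", seq_len(n)), vaf = vaf),
            class = c("paired_patient"))
}

test_that("shared/private partition satisfies the set identities", {
  p <- partition_shared_private(c("a", "b"), c("c"))
  expect_identical(p$shared, character(0))
  expect_setequal(p$private_pre, c("a", "b"))
  expect_identical(p$private_post, "c")
  ident <- partition_shared_private(c("a", "b"), c("a", "b"))
  expect_setequal(ident$shared, c("a", "b"))
  set.seed(71)
  for (i in 1:500) {
    u <- sprintf("k%02d", 1:20)
    pre <- sample(u, sample(0:15, 1))
    post <- sample(u, sample(0:15, 1))
    pp <- partition_shared_private(pre, post)
    expect_identical(length(pp$shared) + length(pp$private_pre),
                     length(unique(pre)))
    expect_identical(length(pp$shared) + length(pp$private_post),
                     length(unique(post)))
    expect_identical(sort(c(pp$shared, pp$private_pre, pp$private_post)),
                     sort(unique(c(pre, post))))
  }
})

test_that("paired VAF matrices key by genomic identity with absent = 0", {
  v <- random_variants(30, seed = 72)
  v$patient_id <- "p1"
  v$sample_id <- paste0("p1_", v$timepoint)
  v <- v[!duplicated(paste(v$sample_id,
                           paste(v$chromosome, v$position, v$ref_allele,
                                 v$alt_allele))), ]
  pp <- paired_patient(v, "p1")
  expect_true(all(pp$vaf >= 0 & pp$vaf <= 1))
  pre_keys <- variant_key(v[v$timepoint == "PRE", ])
  only_pre <- setdiff(pre_keys, variant_key(v[v$timepoint == "POST", ]))
  expect_true(all(pp$vaf[only_pre, "POST"] == 0))
})

test_that("two mutations fall back to a single cluster", {
  vc <- cluster_vafs(paired_from_points(c(0.4, 0.38), c(0.39, 0.41)))
  expect_identical(vc$k, 1L)
  expect_identical(vc$profile, "stable")
})

test_that("well-separated planted clusters are recovered exactly", {
  set.seed(73)
  pre <- c(rnorm(5, 0.5, 0.02), rnorm(5, 0.4, 0.02))
  post <- c(rnorm(5, 0.5, 0.02), rnorm(5, 0.0, 0.005))
  post <- pmax(post, 0)
  vc <- cluster_vafs(paired_from_points(pre, post))
  expect_identical(vc$k, 2L)
  lab <- vc$assignments$cluster
  expect_identical(length(unique(lab[1:5])), 1L)
  expect_identical(length(unique(lab[6:10])), 1L)
  expect_false(lab[1] == lab[6])
  # cluster C1 has the higher mean pre-VAF by construction of the labels
  expect_gte(vc$clusters$mean_pre_vaf[1], vc$clusters$mean_pre_vaf[2])
  expect_identical(vc$clusters$fate, c("retained", "lost"))
  expect_identical(vc$profile, "changed")
})

test_that("agglomeration matches the exhaustive Ward oracle for n <= 8", {
  set.seed(74)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    X <- cbind(runif(n), runif(n))
    d <- stats::dist(X)
    hc <- stats::hclust(d, method = "ward.D2")
    parts <- oracle_ward_partitions(X)
    for (k in seq_len(n - 1)) {
      got <- stats::cutree(hc, k)
      want <- parts[[n - k]]
      expect_true(same_partition(got, want),
                  info = sprintf("iter %d, n %d, k %d", i, n, k))
    }
  }
})

test_that("cluster fates follow the detection-threshold rules", {
  expect_identical(classify_cluster_fate(c(0.4, 0.3), c(0.0, 0.02)), "lost")
  expect_identical(classify_cluster_fate(0.0, 0.3), "emergent")
  expect_identical(classify_cluster_fate(0.3, 0.3), "retained")
  # all members below threshold at both timepoints: retained (never present)
  expect_identical(classify_cluster_fate(0.02, 0.03), "retained")
  expect_identical(classify_patient_profile(c("retained", "retained")),
                   "stable")
  expect_identical(classify_patient_profile(c("retained", "lost",
                                              "retained")), "changed")
})

test_that("clustering is deterministic and scale-stable in merge order", {
  set.seed(75)
  pre <- runif(6, 0, 0.5); post <- runif(6, 0, 0.5)
  a <- cluster_vafs(paired_from_points(pre, post))
  b <- cluster_vafs(paired_from_points(pre, post))
  expect_identical(a$assignments, b$assignments)
  # Euclidean homogeneity: doubling all VAFs preserves the merge order
  hc1 <- stats::hclust(stats::dist(cbind(pre, post)), "ward.D2")
  hc2 <- stats::hclust(stats::dist(cbind(pre, post) * 2), "ward.D2")
  expect_identical(hc1$merge, hc2$merge)
})

test_that("relapse crosstab reproduces printed-count arithmetic", {
  profiles <- data.frame(
    patient_id = sprintf("p%02d", 1:12),
    profile = rep(c("stable", "changed"), c(4, 8)),
    stringsAsFactors = FALSE
  )
  clinical <- data.frame(
    patient_id = sprintf("p%02d", 1:12),
    relapse = c(rep(TRUE, 4), rep(TRUE, 3), rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
  ct <- relapse_crosstab(profiles, clinical)
  expect_identical(ct$table,
                   matrix(c(4L, 0L, 3L, 5L), 2, byrow = TRUE,
                          dimnames = list(c("stable", "changed"),
                                          c("relapse", "no_relapse"))))
  expect_equal(ct$test$p_value,
               oracle_fisher_2x2(4, 0, 3, 5), tolerance = 1e-10)
  clinical$relapse[12] <- NA
  ct2 <- relapse_crosstab(profiles, clinical)
  expect_identical(ct2$excluded, "p12")
  expect_error(relapse_crosstab(profiles[0, ], clinical), "no profiles")
})

test_that("residual cluster enrichment handles empty and exact cases", {
  pre <- c(0.5, 0.5, 0.5, 0.48, 0.52, 0.2, 0.21, 0.19)
  post <- c(0.5, 0.52, 0.49, 0.5, 0.51, 0.0, 0.01, 0.0)
  vc <- cluster_vafs(paired_from_points(pre, post))
  expect_identical(vc$k, 2L)
  universe <- sprintf("GENE%02d", 1:10)
  gs <- gene_set_collection(list(SET_A = sprintf("GENE%02d", 1:5)))
  enr <- residual_cluster_pathways(vc, gs, universe)
  # the lost cluster has no post-mutated genes: not applicable
  lost_cl <- vc$clusters$cluster[vc$clusters$fate == "lost"]
  expect_true(is.na(enr$enriched_terms[enr$cluster == lost_cl]))
  # retained cluster = genes 1..5 = the whole set in a universe of 10
  kept_cl <- vc$clusters$cluster[vc$clusters$fate == "retained"]
  expect_identical(enr$n_post_genes[enr$cluster == kept_cl], 5L)
  expect_match(enr$enriched_terms[enr$cluster == kept_cl], "SET_A")
})

test_that("cohort dynamics ties per-patient calls into profiles", {
  coh <- simulate_cohort(simulation_config(n_patients = 12, pcr_fraction = 0,
                                           seed = 76))
  fr <- apply_filter_cascade(coh$variants)
  dyn <- clonal_dynamics(fr$passed, coh$clinical)
  expect_identical(sort(dyn$profiles$patient_id),
                   sort(names(dyn$patients)))
  expect_true(all(dyn$profiles$profile %in% c("stable", "changed")))
  expect_identical(dim(dyn$crosstab$table), c(2L, 2L))
  expect_identical(nrow(dyn$shared_private), nrow(dyn$profiles))
})
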