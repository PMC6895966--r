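test_that("co-occurrence scan matches enumerated Fisher arithmetic", {
  m <- matrix(0L, 2, 6, dimnames = list(c("A", "B"), sprintf("s%d", 1:6)))
  m[, 1:3] <- 1L  # both genes mutated in exactly the same 3 of 6 samples
  res <- cooccurrence_scan(m)
  expect_identical(nrow(res), 1L)
  expect_identical(res$both, 3L)
  expect_identical(res$neither, 3L)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_identical(res$direction, "co_occurrence")
  expect_error(cooccurrence_scan(m[, 1:2]), "at least 3")
})

test_that("genes below the eligibility floor are excluded from pairs", {
  m <- matrix(c(1, 1, 1, 0, 0,
                1, 0, 0, 0, 0,
                1, 1, 0, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:5)))
  res <- cooccurrence_scan(m, min_mutated_samples = 2)
  expect_setequal(unique(c(res$gene_a, res$gene_b)), c("A", "C"))
})

test_that("pair p-values equal the per-pair Fisher oracle on random data", {
  set.seed(81)
  for (i in 1:10) {
    m <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12,
                dimnames = list(LETTERS[1:8], sprintf("s%02d", 1:12)))
    res <- cooccurrence_scan(m)
    for (r in seq_len(nrow(res))) {
      a <- m[res$gene_a[r], ] == 1; b <- m[res$gene_b[r], ] == 1
      expect_equal(res$p_value[r],
                   oracle_fisher_2x2(sum(a & b), sum(a & !b),
                                     sum(!a & b), sum(!a & !b)),
                   tolerance = 1e-9)
    }
    # symmetry: permuting samples changes nothing
    res_p <- cooccurrence_scan(m[, sample(ncol(m))])
    expect_equal(res[order(res$gene_a, res$gene_b), ]$p_value,
                 res_p[order(res_p$gene_a, res_p$gene_b), ]$p_value)
  }
})

test_that("module extraction equals breadth-1 expansion with components", {
  e <- make_edge_list(c("A", "C"), c("C", "B"))
  mod <- extract_module(c("A", "B"), e)
  expect_setequal(mod$nodes$gene, c("A", "B", "C"))
  expect_identical(nrow(mod$edges), 2L)
  expect_identical(mod$n_components, 1L)
  # isolated seed
  lonely <- extract_module("ZZZ", e)
  expect_identical(lonely$nodes$gene, "ZZZ")
  expect_identical(nrow(lonely$edges), 0L)
  # random graphs against a brute-force first-neighbor oracle
  set.seed(82)
  for (i in 1:20) {
    nodes <- sprintf("N%02d", 1:20)
    a <- sample(nodes, 40, TRUE); b <- sample(nodes, 40, TRUE)
    el <- make_edge_list(a, b)
    seeds <- sample(nodes, sample(1:4, 1))
    mod <- extract_module(seeds, el)
    nbrs <- unique(unlist(lapply(seeds, function(s)
      c(el$gene_b[el$gene_a == s], el$gene_a[el$gene_b == s]))))
    expect_setequal(mod$nodes$gene, union(seeds, nbrs))
    # every non-seed node touches a seed
    non_seed <- mod$nodes$gene[!mod$nodes$is_seed]
    for (x in non_seed)
      expect_true(any(el$gene_a == x & el$gene_b %in% seeds) ||
                    any(el$gene_b == x & el$gene_a %in% seeds))
  }
})

test_that("module extraction is monotone in seeds", {
  set.seed(83)
  nodes <- sprintf("N%02d", 1:15)
  el <- make_edge_list(sample(nodes, 30, TRUE), sample(nodes, 30, TRUE))
  s1 <- c("N01", "N02")
  m1 <- extract_module(s1, el)
  m2 <- extract_module(c(s1, "N05"), el)
  expect_true(all(m1$nodes$gene %in% m2$nodes$gene))
})

test_that("enrichment reproduces closed-form hypergeometric cases", {
  universe <- sprintf("U%02d", 1:10)
  gs <- gene_set_collection(list(SET = universe[1:5]),
                            source = "KEGG")
  res <- enrich_gene_sets(universe[1:5], gs, universe,
                          significant_only = FALSE)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)
  # singleton query in a term covering half the universe
  res2 <- enrich_gene_sets(universe[1], gs, universe,
                           significant_only = FALSE)
  expect_equal(res2$p_value, 0.5, tolerance = 1e-12)
  # query disjoint from all terms: empty result
  res3 <- enrich_gene_sets(universe[6:7], gs, universe,
                           significant_only = FALSE)
  expect_identical(nrow(res3), 0L)
  expect_error(enrich_gene_sets("NOPE", gs, universe), "universe")
})

test_that("enrichment corrects within source at source-specific gates", {
  universe <- sprintf("U%02d", 1:40)
  sets <- c(lapply(1:3, function(i) universe[(4 * i - 3):(4 * i)]),
            list(universe[1:4]))
  names(sets) <- c("K1", "K2", "K3", "G1")
  gs <- gene_set_collection(sets)
  attr(gs, "source") <- c("KEGG", "KEGG", "KEGG", "GO")
  res <- enrich_gene_sets(universe[1:4], gs, universe,
                          significant_only = FALSE)
  expect_identical(sort(unique(res$source)), c("GO", "KEGG"))
  k1 <- res[res$term == "K1", ]; g1 <- res[res$term == "G1", ]
  expect_equal(k1$p_value, g1$p_value)
  # same p, but KEGG q corrected over 3 tested KEGG terms... both overlap>0
  kegg_tested <- sum(res$source == "KEGG")
  expect_identical(kegg_tested, 1L)  # only K1 overlaps the query
})

test_that("enrichment depends only on counts, not gene labels", {
  universe <- sprintf("U%02d", 1:20)
  gs <- gene_set_collection(list(S = universe[1:6]))
  p1 <- enrich_gene_sets(universe[1:3], gs, universe,
                         significant_only = FALSE)$p_value
  relabel <- stats::setNames(sprintf("V%02d", 1:20), universe)
  gs2 <- gene_set_collection(list(S = unname(relabel[universe[1:6]])))
  p2 <- enrich_gene_sets(unname(relabel[universe[1:3]]), gs2,
                         unname(relabel), significant_only = FALSE)$p_value
  expect_equal(p1, p2)
})
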