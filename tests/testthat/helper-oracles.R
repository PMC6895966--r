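# Independent brute-force oracles used to validate the package's statistics
# and algorithms.  These deliberately share no code with the implementation:
# enumeration and direct summation only.

# Two-sided Fisher p by full enumeration of tables with the observed margins.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail by direct summation of the mass function.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exact two-sided rank-sum p by enumeration of all rank splits, using the
# same two-sided doubling convention as the Mann-Whitney U test.
oracle_rank_sum <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  u_all <- apply(splits, 2, function(idx)
    sum(rank(seq_len(n + m))[idx]) - n * (n + 1) / 2)
  p <- if (u_obs > n * m / 2) 2 * mean(u_all >= u_obs)
  else 2 * mean(u_all <= u_obs)
  min(p, 1)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
oracle_signed_rank <- function(x, y) {
  d <- (x - y)[x - y != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p <- if (v_obs > n * (n + 1) / 4) 2 * mean(v_all >= v_obs)
  else 2 * mean(v_all <= v_obs)
  min(p, 1)
}

# Benjamini-Hochberg step-up written directly from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord][j] / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Independent row-wise re-evaluation of the eight filter predicates
# (lenient missing-field handling: a rule with missing required evidence is
# skipped).  Returns TRUE when the variant passes.
oracle_filter_pass <- function(row) {
  fires <- function(x) isTRUE(x)  # NA (missing evidence) never fires
  sub_is_ct <- nchar(row$ref_allele) == 1 && nchar(row$alt_allele) == 1 &&
    row$ref_allele != "-" && row$alt_allele != "-" &&
    paste0(row$ref_allele, row$alt_allele) %in% c("CT", "GA")
  pop <- max(ifelse(is.na(row$pop_af_1kg_eur), 0, row$pop_af_1kg_eur),
             ifelse(is.na(row$pop_af_exac_nfe), 0, row$pop_af_exac_nfe))
  r <- c(
    fires(row$phred_quality < 30),
    fires(row$strand_bias_p < 0.01),
    fires(row$tumor_alt_reads < 7),
    fires(row$tumor_vaf < 0.05 && row$tumor_depth < 500),
    fires(row$tumor_vaf < 0.10 && sub_is_ct),
    pop >= 0.01 && (isTRUE(row$dbsnp_member) || isTRUE(row$normal_depth < 10)),
    fires(row$normal_depth < 10),
    fires(row$normal_vaf >= 0.10)
  )
  !any(r)
}

# Exhaustive Ward (minimum variance increase) agglomeration: returns the
# list of partitions (as integer label vectors) after each merge, from n
# singletons down to one cluster.
oracle_ward_partitions <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  labels <- seq_len(n)
  step <- 0
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      A <- X[clusters[[i]], , drop = FALSE]
      B <- X[clusters[[j]], , drop = FALSE]
      dm <- colMeans(A) - colMeans(B)
      cost <- nrow(A) * nrow(B) / (nrow(A) + nrow(B)) * sum(dm^2)
      if (cost < best[1]) best <- c(cost, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    step <- step + 1
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[step]] <- lab
  }
  partitions
}

# Two partitions agree iff their co-membership relations are equal.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Random variant-record data frame exercising the full field space,
# including exact boundary values for every filter threshold.
random_variants <- function(n, seed = NULL, with_boundaries = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  maybe <- function(x, p_na = 0.15)
    ifelse(runif(n) < p_na, NA, x)
  depth <- sample(c(20:1500), n, replace = TRUE)
  alt <- pmin(depth, stats::rbinom(n, depth, runif(n, 0.01, 0.6)))
  alt <- pmax(alt, 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "x")
  indel <- runif(n) < 0.15
  ref[indel] <- paste0(ref[indel], sample(bases, sum(indel), replace = TRUE))
  df <- data.frame(
    patient_id = sprintf("p%02d", sample(1:10, n, TRUE)),
    sample_id = NA_character_,
    timepoint = sample(c("PRE", "POST"), n, TRUE),
    gene = sample(c("TP53", "PIK3CA", "KRAS", "BRCA1", "NOTCH1"), n, TRUE),
    chromosome = as.character(sample(1:22, n, TRUE)),
    position = sample.int(1e8, n),
    ref_allele = ref, alt_allele = alt_allele,
    variant_type = ifelse(indel, "DEL", "SNV"),
    variant_classification = sample(c("Missense_Mutation", "Silent",
                                      "Nonsense_Mutation", "Splice_Site"),
                                    n, TRUE),
    tumor_depth = depth, tumor_alt_reads = alt, tumor_vaf = alt / depth,
    phred_quality = maybe(round(runif(n, 10, 99), 1)),
    strand_bias_p = maybe(round(runif(n), 4)),
    normal_depth = maybe(sample(c(3:60, 500:900), n, TRUE)),
    normal_vaf = maybe(round(runif(n, 0, 0.6), 4)),
    dbsnp_member = ifelse(runif(n) < 0.15, NA, runif(n) < 0.4),
    pop_af_1kg_eur = maybe(round(runif(n, 0, 0.05), 5)),
    pop_af_exac_nfe = maybe(round(runif(n, 0, 0.05), 5)),
    stringsAsFactors = FALSE
  )
  df$sample_id <- paste0(df$patient_id, "_", df$timepoint)
  if (with_boundaries && n >= 12) {
    # pin every threshold boundary exactly
    df$phred_quality[1] <- 30; df$phred_quality[2] <- 29.9
    df$strand_bias_p[3] <- 0.01
    df$tumor_alt_reads[4] <- 7L; df$tumor_depth[4] <- 700L
    df$tumor_vaf[4] <- 7 / 700
    df$tumor_alt_reads[5] <- 25L; df$tumor_depth[5] <- 500L
    df$tumor_vaf[5] <- 0.05
    df$tumor_alt_reads[6] <- 20L; df$tumor_depth[6] <- 500L  # vaf 0.04, depth 500
    df$tumor_vaf[6] <- 0.04
    df$tumor_alt_reads[7] <- 20L; df$tumor_depth[7] <- 499L
    df$tumor_vaf[7] <- 20 / 499
    df$ref_allele[8] <- "C"; df$alt_allele[8] <- "T"
    df$tumor_alt_reads[8] <- 99L; df$tumor_depth[8] <- 990L
    df$tumor_vaf[8] <- 0.1; df$variant_type[8] <- "SNV"
    df$ref_allele[9] <- "G"; df$alt_allele[9] <- "A"
    df$tumor_alt_reads[9] <- 90L; df$tumor_depth[9] <- 1000L
    df$tumor_vaf[9] <- 0.09; df$variant_type[9] <- "SNV"
    df$pop_af_1kg_eur[10] <- 0.01; df$dbsnp_member[10] <- TRUE
    df$normal_depth[11] <- 10L
    df$normal_vaf[12] <- 0.10
  }
  # unique keys within sample
  dup <- duplicated(paste(df$sample_id, df$chromosome, df$position,
                          df$ref_allele, df$alt_allele))
  df$position[dup] <- df$position[dup] + sample.int(1e6, sum(dup))
  df
}
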