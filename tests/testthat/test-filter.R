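clean_record <- function(...) {
  base <- data.frame(
    patient_id = "p01", sample_id = "p01_PRE", timepoint = "PRE",
    gene = "TP53", chromosome = "17", position = 7578406L,
    ref_allele = "G", alt_allele = "C", variant_type = "SNV",
    variant_classification = "Missense_Mutation",
    tumor_depth = 1000L, tumor_alt_reads = 300L, tumor_vaf = 0.3,
    phred_quality = 80, strand_bias_p = 0.5, normal_depth = 800L,
    normal_vaf = 0.001, dbsnp_member = FALSE,
    pop_af_1kg_eur = NA_real_, pop_af_exac_nfe = NA_real_,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

failed <- function(rec, ...) {
  out <- evaluate_rules(rec, ...)
  strsplit(out$failed_rules, ",")[[1]]
}

test_that("impact classification follows the controlled vocabulary", {
  expect_identical(classify_impact("Missense_Mutation"), "MODERATE")
  expect_identical(classify_impact("Frame_Shift_Del"), "HIGH")
  expect_identical(classify_impact("Silent"), "LOW")
  expect_identical(classify_impact("3'UTR"), "MODIFIER")
  expect_identical(classify_impact("Banana"), "MODIFIER")
  expect_error(classify_impact("Banana", strict = TRUE), "unknown")
})

test_that("substitution classes merge strands onto pyrimidine context", {
  expect_identical(substitution_class("G", "A"), "C>T/G>A")
  expect_identical(substitution_class("C", "T"), "C>T/G>A")
  expect_identical(substitution_class("A", "C"), "T>G/A>C")
  expect_identical(substitution_class("T", "G"), "T>G/A>C")
  expect_identical(substitution_class("AT", "A"), "NOT_SNV")
  expect_identical(substitution_class("A", "ATT"), "NOT_SNV")
  expect_error(substitution_class("N", "A"), "non-ACGT")
  # all 12 ordered substitutions land in 6 classes, 2 each
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(r = bases, a = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  cls <- substitution_class(pairs$r, pairs$a)
  expect_identical(length(unique(cls)), 6L)
  expect_true(all(table(cls) == 2))
})

test_that("each rule fires exactly on its printed condition and boundary", {
  expect_identical(failed(clean_record()), character(0))
  expect_identical(failed(clean_record(phred_quality = 25)), "R1")
  expect_identical(failed(clean_record(phred_quality = 30)), character(0))
  expect_identical(failed(clean_record(strand_bias_p = 0.005)), "R2")
  expect_identical(failed(clean_record(strand_bias_p = 0.01)), character(0))
  expect_identical(failed(clean_record(tumor_alt_reads = 6L,
                                       tumor_vaf = 0.006,
                                       tumor_depth = 1000L)), "R3")
  # deep coverage rescues low VAF (R4 needs depth < 500)
  expect_identical(failed(clean_record(tumor_vaf = 0.04,
                                       tumor_alt_reads = 24L,
                                       tumor_depth = 600L)), character(0))
  expect_identical(failed(clean_record(tumor_vaf = 0.04,
                                       tumor_alt_reads = 18L,
                                       tumor_depth = 450L)), "R4")
  # boundary: VAF exactly 0.05 passes R4 regardless of depth
  expect_identical(failed(clean_record(tumor_vaf = 0.05,
                                       tumor_alt_reads = 20L,
                                       tumor_depth = 400L)), character(0))
  # FFPE signature: C>T below 10% VAF
  expect_identical(failed(clean_record(ref_allele = "C", alt_allele = "T",
                                       tumor_vaf = 0.08,
                                       tumor_alt_reads = 80L,
                                       tumor_depth = 1000L)), "R5")
  expect_identical(failed(clean_record(ref_allele = "C", alt_allele = "T",
                                       tumor_vaf = 0.10,
                                       tumor_alt_reads = 100L,
                                       tumor_depth = 1000L)), character(0))
  expect_identical(failed(clean_record(ref_allele = "A", alt_allele = "G",
                                       tumor_vaf = 0.08,
                                       tumor_alt_reads = 80L,
                                       tumor_depth = 1000L)), character(0))
  # common allele + dbSNP
  expect_identical(failed(clean_record(pop_af_1kg_eur = 0.02,
                                       dbsnp_member = TRUE)), "R6")
  expect_identical(failed(clean_record(pop_af_1kg_eur = 0.01,
                                       dbsnp_member = TRUE)), "R6")
  expect_identical(failed(clean_record(pop_af_1kg_eur = 0.009,
                                       dbsnp_member = TRUE)), character(0))
  expect_identical(failed(clean_record(pop_af_exac_nfe = 0.02,
                                       dbsnp_member = FALSE)),
                   character(0))  # common but neither dbSNP nor shallow normal
  expect_setequal(failed(clean_record(pop_af_exac_nfe = 0.02,
                                      normal_depth = 8L)),
                  c("R6", "R7"))
  expect_identical(failed(clean_record(normal_depth = 9L)), "R7")
  expect_identical(failed(clean_record(normal_depth = 10L)), character(0))
  expect_identical(failed(clean_record(normal_vaf = 0.12)), "R8")
  expect_identical(failed(clean_record(normal_vaf = 0.10)), "R8")
  expect_identical(failed(clean_record(normal_vaf = 0.099)), character(0))
})

test_that("the alternate reading of the population rule is available", {
  rec <- clean_record(dbsnp_member = TRUE)  # rare dbSNP variant
  expect_identical(failed(rec), character(0))
  expect_identical(failed(rec, r6_parse = "dbsnp_or_lowdepth_and_af"), "R6")
})

test_that("missing evidence skips rules in lenient mode, discards in strict", {
  rec <- clean_record(phred_quality = NA_real_)
  out_len <- evaluate_rules(rec)
  expect_true(out_len$passed)
  expect_match(out_len$skipped_rules, "R1")
  res <- apply_filter_cascade(rec, mode = "strict")
  expect_identical(nrow(res$passed), 0L)
  expect_true(res$outcomes$discarded_missing)
})

test_that("cascade equals the independent per-record oracle on 1000 records", {
  v <- random_variants(1000, seed = 202)
  res <- apply_filter_cascade(v)
  oracle <- vapply(seq_len(nrow(v)), function(i)
    oracle_filter_pass(v[i, ]), logical(1))
  expect_identical(res$outcomes$passed, oracle)
  # completeness: every record in exactly one of passed/discarded
  expect_identical(nrow(res$passed) + nrow(res$discarded), nrow(v))
  # audit: every discarded record lists at least one failed rule
  expect_true(all(nzchar(res$outcomes$failed_rules[!res$outcomes$passed])))
  expect_true(all(res$outcomes$failed_rules[res$outcomes$passed] == ""))
})

test_that("filtering is idempotent", {
  v <- random_variants(500, seed = 203)
  first <- apply_filter_cascade(v)
  second <- apply_filter_cascade(first$passed)
  expect_identical(nrow(second$passed), nrow(first$passed))
  expect_true(all(second$outcomes$failed_rules == ""))
})

test_that("relaxing any single threshold never shrinks the passed set", {
  v <- random_variants(400, seed = 204)
  base_pass <- apply_filter_cascade(v)$outcomes$passed
  relaxed <- list(
    filter_thresholds(phred_min = 20),
    filter_thresholds(strand_bias_p_min = 0.001),
    filter_thresholds(alt_reads_min = 3),
    filter_thresholds(low_vaf = 0.02),
    filter_thresholds(depth_rescue = 300),
    filter_thresholds(ffpe_vaf = 0.05),
    filter_thresholds(pop_af_max = 0.05),
    filter_thresholds(normal_depth_min = 5),
    filter_thresholds(normal_vaf_max = 0.2)
  )
  for (th in relaxed) {
    pass <- apply_filter_cascade(v, thresholds = th)$outcomes$passed
    expect_true(all(pass[base_pass]))
  }
})
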