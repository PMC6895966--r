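# Representative cancer-gene symbol pool for simulation.  A curated subset of
# genes commonly covered by comprehensive cancer panels — not the membership
# of any specific commercial panel.
.gene_pool <- c(
  "TP53", "PIK3CA", "KRAS", "NRAS", "HRAS", "BRAF", "EGFR", "ERBB2", "ERBB3",
  "ERBB4", "PTEN", "AKT1", "AKT2", "AKT3", "MTOR", "RICTOR", "RPTOR", "STK11",
  "TSC1", "TSC2", "RB1", "CDKN2A", "CDKN1B", "CDK4", "CDK6", "CCND1", "CCNE1",
  "MYC", "MYCN", "MYCL", "NOTCH1", "NOTCH2", "NOTCH3", "FBXW7", "CREBBP",
  "EP300", "KMT2A", "KMT2C", "KMT2D", "ARID1A", "ARID1B", "ARID2", "SMARCA4",
  "SMARCB1", "PBRM1", "SETD2", "KDM6A", "KDM5C", "BRCA1", "BRCA2", "PALB2",
  "ATM", "ATR", "CHEK1", "CHEK2", "BAP1", "MLH1", "MSH2", "MSH6", "PMS2",
  "POLE", "POLD1", "FANCA", "FANCC", "FANCD2", "APC", "CTNNB1", "AXIN1",
  "AXIN2", "TCF7L1", "TCF7L2", "SOX9", "SOX11", "GATA3", "FOXA1", "RUNX1",
  "CEBPA", "NPM1", "FLT3", "KIT", "PDGFRA", "PDGFRB", "MET", "ALK", "ROS1",
  "RET", "NTRK1", "NTRK2", "NTRK3", "FGFR1", "FGFR2", "FGFR3", "FGFR4",
  "IGF1R", "JAK1", "JAK2", "JAK3", "TYK2", "STAT3", "STAT5B", "MAP2K1",
  "MAP2K2", "MAP2K4", "MAP3K1", "MAPK1", "NF1", "NF2", "SPEN", "SF3B1",
  "U2AF1", "SRSF2", "ZRSR2", "LTK", "TAF1L", "SYNE1", "LRP1B", "MYH11",
  "BCL9", "FN1", "IKBKB", "RNASEL", "CARD11", "REL", "KEAP1", "NFE2L2",
  "TGFBR2", "SMAD4", "VHL", "WT1", "DNMT3A", "TET2", "IDH1", "IDH2", "EZH2",
  "SUZ12", "ASXL1", "BCOR", "KDR", "TPR", "NUP214", "ITGB2", "GPR124"
)

#' Simulation configuration for synthetic cohorts
#'
#' Defines the statistical structure of a simulated paired pre/post-treatment
#' panel-sequencing cohort: clonal sub-populations with treatment-induced
#' cancer-cell-fraction (CCF) shifts, overdispersed read depths with binomial
#' allele sampling, low-VAF FFPE deamination artifacts, germline
#' leak-throughs, and clinical response / relapse labels.
#'
#' The defaults emulate a small neoadjuvant triple-negative breast cancer
#' cohort: ~21% pCR rate, a long-tailed mutation count per patient (median 4,
#' range clamped to `mutations_per_patient`), TP53 mutated in 87% of
#' pre-treatment samples, 1-4 clones per tumor, ~800x mean depth, purity 0.6,
#' two thirds of residual-disease patients with a changed (lost or emergent
#' clone) profile, relapse probability 1 for stable-profile patients, 0.375
#' for changed, 0 for pCR.
#'
#' @param n_patients Number of patients.
#' @param pcr_fraction Probability a patient attains pathological complete
#'   response (pCR patients have no post-treatment sample).
#' @param mutations_per_patient Integer range `c(min, max)` clamping the
#'   per-patient somatic mutation count.
#' @param n_clones Integer range for the number of clones per tumor (capped
#'   at the patient's mutation count).
#' @param depth_mean Mean sequencing depth (reads).
#' @param depth_overdispersion Negative-binomial size parameter for depth.
#' @param purity Tumor purity; expected VAF is `purity * CCF / 2`
#'   (diploid heterozygous model).
#' @param ffpe_artifact_rate Expected FFPE artifacts injected per sample.
#' @param germline_rate Expected germline leak-throughs injected per sample.
#' @param prob_changed Probability a residual-disease patient has a planted
#'   changed profile (one clone lost after treatment or emergent).
#' @param tp53_rate Probability a patient carries a clonal TP53 mutation.
#' @param relapse_prob Named vector of relapse probabilities for
#'   `stable`, `changed`, and `pCR` patients.
#' @param mutation_nb_mu,mutation_nb_size Mean and size of the shifted
#'   negative binomial generating per-patient somatic mutation counts
#'   (`1 + NB(size, mu)`, clamped to `mutations_per_patient`).  Defaults are
#'   calibrated so the observed — post-filter, high/moderate-impact —
#'   per-sample burden has median about 4 with a long upper tail.
#' @param seed Integer seed; per-patient substreams are derived from it by
#'   fixed offsets, so the cohort is bit-reproducible.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_patients = 19L,
                              pcr_fraction = 4 / 19,
                              mutations_per_patient = c(1L, 66L),
                              n_clones = c(1L, 4L),
                              depth_mean = 800,
                              depth_overdispersion = 8,
                              purity = 0.6,
                              ffpe_artifact_rate = 3,
                              germline_rate = 2,
                              prob_changed = 8 / 12,
                              tp53_rate = 0.87,
                              relapse_prob = c(stable = 1, changed = 0.375,
                                               pCR = 0),
                              mutation_nb_mu = 7,
                              mutation_nb_size = 0.9,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_patients >= 1,
    pcr_fraction >= 0, pcr_fraction <= 1,
    length(mutations_per_patient) == 2, mutations_per_patient[1] >= 1,
    mutations_per_patient[2] >= mutations_per_patient[1],
    length(n_clones) == 2, n_clones[1] >= 1, n_clones[2] >= n_clones[1],
    depth_mean > 0, depth_overdispersion > 0,
    purity > 0, purity <= 1,
    ffpe_artifact_rate >= 0, germline_rate >= 0,
    prob_changed >= 0, prob_changed <= 1,
    tp53_rate >= 0, tp53_rate <= 1,
    all(c("stable", "changed", "pCR") %in% names(relapse_prob))
  )
  structure(cfg, class = "simulation_config")
}

.substream <- function(seed, index, stream = 0L) {
  set.seed((as.integer(seed) + 7919L * as.integer(index) +
              104729L * as.integer(stream)) %% 2147483647L)
}

#' Sample read counts at a locus
#'
#' Depth is drawn from a shifted negative binomial with the requested mean
#' (support starts at 1 read), and alternate reads from a binomial at the
#' true allele fraction, so `alt_reads <= depth` always.
#'
#' @param true_vaf True allele fraction(s) in \[0, 1\].
#' @param depth_mean Mean depth (> 0).
#' @param overdispersion Negative-binomial size parameter.
#' @param n Number of draws (recycled against `true_vaf`).
#' @return A data frame with columns `depth` and `alt_reads`.
#' @export
simulate_read_counts <- function(true_vaf, depth_mean = 800,
                                 overdispersion = 8, n = length(true_vaf)) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (any(true_vaf < 0 | true_vaf > 1)) stop("true_vaf must lie in [0, 1]")
  true_vaf <- rep_len(true_vaf, n)
  depth <- 1L + stats::rnbinom(n, size = overdispersion, mu = depth_mean - 1)
  alt <- stats::rbinom(n, depth, true_vaf)
  data.frame(depth = depth, alt_reads = alt)
}

# Stick-breaking clone CCFs, rescaled so the largest clone is clonal (CCF 1).
.draw_ccfs <- function(k) {
  if (k == 1) return(1)
  sticks <- numeric(k)
  remaining <- 1
  for (j in seq_len(k)) {
    frac <- stats::rbeta(1, 1, 2)
    sticks[j] <- remaining * frac
    remaining <- remaining - sticks[j]
  }
  sticks <- sort(sticks, decreasing = TRUE)
  sticks / sticks[1]
}

.classifications <- c(
  Missense_Mutation = 0.60, Nonsense_Mutation = 0.09, Splice_Site = 0.08,
  Frame_Shift_Del = 0.05, Frame_Shift_Ins = 0.04, In_Frame_Del = 0.02,
  In_Frame_Ins = 0.01, Nonstop_Mutation = 0.01, Silent = 0.07, `3'UTR` = 0.03
)

.random_alleles <- function(classification) {
  bases <- c("A", "C", "G", "T")
  if (classification %in% c("Frame_Shift_Del", "In_Frame_Del")) {
    len <- if (classification == "In_Frame_Del") 4L else
      sample(c(2L, 3L), 1)  # 1 or 2 deleted bases after the anchor
    ref <- paste(sample(bases, len, replace = TRUE), collapse = "")
    list(ref = ref, alt = substr(ref, 1, 1), type = "DEL")
  } else if (classification %in% c("Frame_Shift_Ins", "In_Frame_Ins")) {
    len <- if (classification == "In_Frame_Ins") 3L else sample(c(1L, 2L), 1)
    anchor <- sample(bases, 1)
    list(ref = anchor,
         alt = paste(c(anchor, sample(bases, len, replace = TRUE)),
                     collapse = ""),
         type = "INS")
  } else {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    list(ref = ref, alt = alt, type = "SNV")
  }
}

.clean_evidence <- function(depth_mean, overdispersion) {
  ndepth <- 1L + stats::rnbinom(1, size = overdispersion, mu = depth_mean - 1)
  nalt <- stats::rbinom(1, ndepth, 0.002)
  dbsnp <- stats::runif(1) < 0.03
  list(
    phred_quality = round(stats::runif(1, 33, 99), 1),
    strand_bias_p = round(stats::runif(1, 0.02, 1), 4),
    normal_depth = ndepth,
    normal_vaf = nalt / ndepth,
    dbsnp_member = dbsnp,
    pop_af_1kg_eur = if (dbsnp) stats::runif(1, 0, 0.005) else NA_real_,
    pop_af_exac_nfe = if (dbsnp && stats::runif(1) < 0.5)
      stats::runif(1, 0, 0.005) else NA_real_
  )
}

.variant_row <- function(patient, timepoint, gene, chromosome, position,
                         alleles, classification, depth, alt, evidence) {
  data.frame(
    patient_id = patient,
    sample_id = paste0(patient, "_", timepoint),
    timepoint = timepoint,
    gene = gene, chromosome = chromosome, position = position,
    ref_allele = alleles$ref, alt_allele = alleles$alt,
    variant_type = alleles$type,
    variant_classification = classification,
    tumor_depth = depth, tumor_alt_reads = alt, tumor_vaf = alt / depth,
    phred_quality = evidence$phred_quality,
    strand_bias_p = evidence$strand_bias_p,
    normal_depth = evidence$normal_depth,
    normal_vaf = evidence$normal_vaf,
    dbsnp_member = evidence$dbsnp_member,
    pop_af_1kg_eur = evidence$pop_af_1kg_eur,
    pop_af_exac_nfe = evidence$pop_af_exac_nfe,
    stringsAsFactors = FALSE
  )
}

.simulate_patient <- function(cfg, index) {
  .substream(cfg$seed, index)
  patient <- sprintf("p%02d", index)
  is_pcr <- stats::runif(1) < cfg$pcr_fraction
  timepoints <- if (is_pcr) "PRE" else c("PRE", "POST")
  profile <- if (is_pcr) NA_character_ else
    if (stats::runif(1) < cfg$prob_changed) "changed" else "stable"

  n_mut <- min(max(1L + stats::rnbinom(1, size = cfg$mutation_nb_size,
                                       mu = cfg$mutation_nb_mu),
                   cfg$mutations_per_patient[1]),
               cfg$mutations_per_patient[2])
  k_range <- seq(cfg$n_clones[1], cfg$n_clones[2])
  k <- if (length(k_range) == 1) k_range else sample(k_range, 1)
  if (identical(profile, "changed")) {
    # a changed profile needs a planted lost/emergent clone alongside a
    # retained one, hence >= 2 clones each carrying >= 1 mutation
    n_mut <- max(n_mut, 2L)
    n_mut <- min(n_mut, cfg$mutations_per_patient[2])
    k <- max(k, 2L)
  }
  k <- min(k, n_mut)
  if (identical(profile, "changed") && k < 2L)
    profile <- "stable"  # unplantable under the configured ranges
  ccf_pre <- .draw_ccfs(k)
  ccf_post <- pmin(pmax(ccf_pre + stats::runif(k, -0.025, 0.025), 0), 1)
  direction <- NA_character_
  planted <- NA_integer_
  if (identical(profile, "changed") && k >= 2) {
    planted <- k  # the planted clone is the smallest stick
    direction <- sample(c("lost", "emergent"), 1)
    if (direction == "lost") {
      ccf_pre[planted] <- stats::runif(1, 0.4, 0.9)
      ccf_post[planted] <- 0
    } else {
      ccf_pre[planted] <- 0
      ccf_post[planted] <- stats::runif(1, 0.4, 0.9)
    }
  }

  clone <- sample.int(k, n_mut, replace = TRUE)
  clone[1] <- 1L  # the clonal cluster is never empty
  if (!is.na(planted) && !any(clone == planted))
    clone[n_mut] <- as.integer(planted)

  genes <- sample(setdiff(.gene_pool, "TP53"), min(n_mut, 100),
                  replace = n_mut > 100)
  genes <- rep_len(genes, n_mut)
  if (stats::runif(1) < cfg$tp53_rate) genes[1] <- "TP53"

  chromosome <- as.character(sample.int(22, n_mut, replace = TRUE))
  position <- sample.int(2e8L, n_mut)
  classification <- sample(names(.classifications), n_mut, replace = TRUE,
                           prob = .classifications)

  rows <- list(); truth <- list(); r <- 0L
  for (m in seq_len(n_mut)) {
    alleles <- .random_alleles(classification[m])
    evidence <- .clean_evidence(cfg$depth_mean, cfg$depth_overdispersion)
    for (tp in timepoints) {
      ccf <- if (tp == "PRE") ccf_pre[clone[m]] else ccf_post[clone[m]]
      true_vaf <- cfg$purity * ccf / 2
      rc <- simulate_read_counts(true_vaf, cfg$depth_mean,
                                 cfg$depth_overdispersion, n = 1)
      if (rc$alt_reads < 1) next
      r <- r + 1L
      rows[[r]] <- .variant_row(patient, tp, genes[m], chromosome[m],
                                position[m], alleles, classification[m],
                                rc$depth, rc$alt_reads, evidence)
      truth[[r]] <- data.frame(
        patient_id = patient, sample_id = paste0(patient, "_", tp),
        key = paste0(chromosome[m], ":", position[m], ":",
                     alleles$ref, ">", alleles$alt),
        gene = genes[m], label = "true_somatic", clone = clone[m],
        true_vaf = true_vaf, stringsAsFactors = FALSE
      )
    }
  }

  list(
    variants = if (r) do.call(rbind, rows) else NULL,
    truth = if (r) do.call(rbind, truth) else NULL,
    clinical = data.frame(
      patient_id = patient,
      age_years = round(stats::runif(1, 32, 75)),
      response = if (is_pcr) "pCR" else "RD",
      relapse = stats::runif(1) < cfg$relapse_prob[[
        if (is_pcr) "pCR" else profile]],
      stage = sample(c("II", "III"), 1, prob = c(0.85, 0.15)),
      grade = sample(c("G2", "G3"), 1, prob = c(0.05, 0.95)),
      stils_pre = round(stats::runif(1, 3, 30), 1),
      stils_post = if (is_pcr) NA_real_ else round(stats::runif(1, 3, 50), 1),
      stringsAsFactors = FALSE
    ),
    profile = data.frame(
      patient_id = patient,
      response = if (is_pcr) "pCR" else "RD",
      true_profile = profile, planted_direction = direction,
      n_clones = k, n_mutations = n_mut, stringsAsFactors = FALSE
    )
  )
}

#' Inject FFPE artifacts and germline leak-throughs
#'
#' Adds two classes of known false calls to a variant table, with truth
#' labels.  FFPE artifacts are C>T or G>A substitutions with true VAF drawn
#' uniformly on (0.01, 0.09) — the low-frequency cytosine-deamination
#' signature.  Germline leak-throughs carry a normal-sample VAF drawn
#' uniformly on (0.35, 0.65) and a European population allele frequency of
#' at least 1% with probability 0.8.
#'
#' @param variants Variant data frame (the true-somatic rows).
#' @param config A [simulation_config()].
#' @return A list with `variants` (input rows plus injected rows) and
#'   `truth` (labels for the injected rows only).
#' @export
inject_artifacts <- function(variants, config) {
  samples <- unique(variants$sample_id)
  rows <- list(); truth <- list(); r <- 0L
  for (si in seq_along(samples)) {
    .substream(config$seed, si, stream = 1L)
    sid <- samples[si]
    patient <- sub("_(PRE|POST)$", "", sid)
    tp <- sub("^.*_", "", sid)
    n_ffpe <- stats::rpois(1, config$ffpe_artifact_rate)
    n_germ <- stats::rpois(1, config$germline_rate)
    for (j in seq_len(n_ffpe + n_germ)) {
      is_ffpe <- j <= n_ffpe
      gene <- sample(.gene_pool, 1)
      chromosome <- as.character(sample.int(22, 1))
      position <- sample.int(2e8L, 1)
      if (is_ffpe) {
        alleles <- if (stats::runif(1) < 0.5)
          list(ref = "C", alt = "T", type = "SNV")
        else list(ref = "G", alt = "A", type = "SNV")
        true_vaf <- stats::runif(1, 0.01, 0.09)
        evidence <- .clean_evidence(config$depth_mean,
                                    config$depth_overdispersion)
        classification <- "Missense_Mutation"
      } else {
        b <- sample(c("A", "C", "G", "T"), 1)
        alleles <- list(ref = b, alt = sample(setdiff(c("A", "C", "G", "T"),
                                                      b), 1), type = "SNV")
        true_vaf <- 0.5
        evidence <- .clean_evidence(config$depth_mean,
                                    config$depth_overdispersion)
        evidence$normal_vaf <- stats::runif(1, 0.35, 0.65)
        evidence$dbsnp_member <- stats::runif(1) < 0.9
        evidence$pop_af_1kg_eur <- if (stats::runif(1) < 0.8)
          stats::runif(1, 0.01, 0.5) else stats::runif(1, 0, 0.005)
        classification <- sample(c("Missense_Mutation", "Silent"), 1,
                                 prob = c(0.7, 0.3))
      }
      rc <- simulate_read_counts(true_vaf, config$depth_mean,
                                 config$depth_overdispersion, n = 1)
      if (rc$alt_reads < 1) next
      r <- r + 1L
      rows[[r]] <- .variant_row(patient, tp, gene, chromosome, position,
                                alleles, classification,
                                rc$depth, rc$alt_reads, evidence)
      truth[[r]] <- data.frame(
        patient_id = patient, sample_id = sid,
        key = paste0(chromosome, ":", position, ":",
                     alleles$ref, ">", alleles$alt),
        gene = gene, label = if (is_ffpe) "ffpe_artifact" else "germline",
        clone = NA_integer_, true_vaf = true_vaf, stringsAsFactors = FALSE
      )
    }
  }
  list(
    variants = rbind(variants, if (r) do.call(rbind, rows)),
    truth = if (r) do.call(rbind, truth) else NULL
  )
}

#' Simulate a paired pre/post-treatment panel-sequencing cohort
#'
#' Generates a full synthetic cohort with ground truth: per-patient clonal
#' structure with planted stable or changed (lost/emergent clone) profiles,
#' binomial read sampling over negative-binomial depths, FFPE artifacts,
#' germline leak-throughs, and a clinical sheet.  pCR patients have no
#' post-treatment sample (no residual tumor to sequence).  A variant is
#' emitted at a timepoint only if at least one alternate read was sampled,
#' so lost clones vanish from post-treatment tables and emergent clones are
#' absent pre-treatment.  Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"synthetic_cohort"`: a list with `variants`
#'   (pre-filter variant table, both timepoints), `clinical`, `truth` (one
#'   label per variant row: `true_somatic`, `ffpe_artifact`, or `germline`,
#'   plus clone assignment and true VAF), and `profiles` (per-patient planted
#'   `stable`/`changed` truth), plus the `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  per_patient <- lapply(seq_len(config$n_patients), function(i)
    .simulate_patient(config, i))
  variants <- do.call(rbind, lapply(per_patient, `[[`, "variants"))
  truth <- do.call(rbind, lapply(per_patient, `[[`, "truth"))
  injected <- inject_artifacts(variants, config)
  rownames(injected$variants) <- NULL
  truth <- rbind(truth, injected$truth)
  rownames(truth) <- NULL
  out <- list(
    variants = injected$variants,
    clinical = do.call(rbind, lapply(per_patient, `[[`, "clinical")),
    truth = truth,
    profiles = do.call(rbind, lapply(per_patient, `[[`, "profile")),
    config = config
  )
  validate_variants(out$variants)
  stopifnot(nrow(out$truth) == nrow(out$variants))
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$clinical), "patients,",
      nrow(x$variants), "variant rows\n")
  cat("  truth labels:",
      paste(names(table(x$truth$label)), table(x$truth$label),
            sep = "=", collapse = ", "), "\n")
  cat("  responses:",
      paste(names(table(x$clinical$response)), table(x$clinical$response),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
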