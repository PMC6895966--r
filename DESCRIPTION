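Package: mutdyn
Title: Somatic Mutation Dynamics in Paired Pre/Post-Treatment Tumor Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for targeted-panel somatic mutation data from
    paired pre- and post-neoadjuvant-chemotherapy tumor samples.  Provides an
    FFPE-aware eight-rule somatic variant filter cascade, mutational landscape
    summaries (burden, substitution spectrum, recurrently mutated genes),
    gene- and pathway-level association with treatment response via Fisher's
    exact test, per-patient clustering of paired variant allele frequencies
    with clonal fate calls (retained, lost, emergent) and stable-vs-changed
    profile classification, mutation co-occurrence scans with protein-protein
    interaction module extraction and gene-set enrichment, plus a synthetic
    cohort simulator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    igraph,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
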