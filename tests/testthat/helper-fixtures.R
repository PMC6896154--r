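# Shared in-code fixtures: tiny assays with known structure, and a scaled
# cohort config for tests that do not need the full default world.

tiny_beta <- function() {
  beta <- matrix(c(0.5, 0.125, 0.8,
                   0.2, 0.2, 0.2,
                   0.9, 0.4, 0.6), nrow = 3, byrow = TRUE,
                 dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2", "s3")))
  methylation_assay(beta)
}

tiny_annotation <- function() {
  cpg_annotation(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    chrom = c("chr1", "chr1", "chr2", "chr3"),
    position = c(100L, 200L, 300L, 400L),
    entries = data.frame(
      probe_id = c("cg1", "cg1", "cg2"),
      gene = c("GENEA", "GENEB", "GENEA"),
      region = c("TSS200", "Body", "TSS200"),
      stringsAsFactors = FALSE
    )
  )
}

# Balanced two-group sheet for n samples named s1..sn (first half = case).
tiny_samples <- function(n = 4, ids = paste0("s", seq_len(n))) {
  sample_sheet(ids, rep(c("case", "control"), each = n / 2))
}

# Small, fast cohort: 60 genes, 10 planted, 20+20 samples.
small_sim_config <- function(seed, ...) {
  simulation_config(
    n_case = 20L, n_control = 20L, n_genes = 60L,
    n_intergenic_cpgs = 40L,
    planted = default_planted_effects(60L, n_planted = 10L),
    seed = seed, ...
  )
}

# Feature matrix (samples x probes) of the DMSs inside DMEGs for a cohort.
dms_feature_matrix <- function(cohort, site_diff, dmegs) {
  probes <- unique(dms_in_dmegs(site_diff, dmegs, cohort$annotation)$probe_id)
  t(cohort$methylation$beta[probes, cohort$samples$sample_id, drop = FALSE])
}
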