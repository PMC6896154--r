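#' Normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills defaults and reports any
#' threshold overridden away from the canonical values
#' (adj p < 0.05, |delta beta| > 0.2, adj p < 0.05, |log2FC| > 2).
#'
#' @param config YAML path or list. Recognized fields: `simulate` (logical)
#'   or input paths (`beta`, `annotation`, `expression`, `samples`),
#'   `sim` (overrides passed to [simulation_config()]), `regions`,
#'   `thresholds` (`meth_adj_p`, `delta_beta`, `expr_adj_p`, `log2fc`),
#'   `classifier` (`name`, `n_trees`), `strata`, `drug_table`,
#'   `category_map`, `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    simulate = is.null(config$beta),
    sim = list(),
    regions = DEFAULT_REGIONS,
    thresholds = list(meth_adj_p = 0.05, delta_beta = 0.2,
                      expr_adj_p = 0.05, log2fc = 2),
    classifier = list(name = "random_forest", n_trees = 500L),
    strata = c("age", "menopause", "race", "stage"),
    drug_table = NULL, category_map = NULL,
    seed = 1L
  )
  out <- utils::modifyList(defaults, config)
  canonical <- defaults$thresholds
  for (k in names(canonical)) {
    if (!identical(as.numeric(out$thresholds[[k]]), as.numeric(canonical[[k]]))) {
      message(sprintf("pipeline_config: threshold %s overridden to %s (canonical %s)",
                      k, out$thresholds[[k]], canonical[[k]]))
    }
  }
  class(out) <- "pipeline_config"
  out
}

#' Run the full coupled methylation + expression pipeline
#'
#' Stages: input (simulated cohort or files) -> site- and region-level
#' differential methylation -> differential expression -> DMG/DEG/DMEG
#' integration -> LOOCV/ROC evaluation of the DMS-methylation and
#' DMEG-expression feature sets with covariate stratification -> drug-target
#' mapping of upregulated DMEGs. All stage tables are written under
#' `out_dir` along with `manifest.json` (thresholds, per-stage counts,
#' output checksums); deterministic given inputs and `config$seed`.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage objects plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds

  # --- stage: input ---
  if (isTRUE(config$simulate)) {
    sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
    cohort <- generate_cohort(do.call(simulation_config, sim_args))
  } else {
    cohort <- read_assays(beta_path = config$beta,
                          annotation_path = config$annotation,
                          expression_path = config$expression,
                          sample_sheet_path = config$samples)
    cohort$truth <- NULL
  }

  # --- stage: differential methylation (sites + regions) ---
  site_diff <- diff_methylation(cohort$methylation, cohort$samples,
                                p_cut = th$meth_adj_p, effect_cut = th$delta_beta)
  regmeth <- aggregate_regions(cohort$methylation, cohort$annotation,
                               regions = config$regions)
  region_diff <- diff_methylation(regmeth, cohort$samples,
                                  p_cut = th$meth_adj_p, effect_cut = th$delta_beta)
  dmgs <- derive_dmgs(region_diff, regions = config$regions)

  # --- stage: differential expression ---
  expr_diff <- diff_expression(cohort$expression, cohort$samples,
                               p_cut = th$expr_adj_p, effect_cut = th$log2fc)

  # --- stage: integration ---
  dmegs <- suppressWarnings(
    build_dmeg_table(region_diff, expr_diff, p_cut = th$meth_adj_p,
                     beta_cut = th$delta_beta, fc_cut = th$log2fc)
  )
  dms_set <- dms_in_dmegs(site_diff, dmegs, cohort$annotation)

  # --- stage: evaluation ---
  labels <- as.character(cohort$samples$group)
  clf <- config$classifier$name
  n_trees <- config$classifier$n_trees
  evaluations <- list()
  strata_reports <- list()
  if (nrow(dms_set) > 0L) {
    probes <- unique(dms_set$probe_id)
    feats <- t(cohort$methylation$beta[probes, cohort$samples$sample_id, drop = FALSE])
    evaluations$dms <- evaluate_feature_set(feats, labels, "dms_methylation",
                                            classifier = clf, n_trees = n_trees,
                                            seed = config$seed)
    strata_reports$dms <- .run_strata(feats, labels, cohort$samples, config)
  } else {
    warning("no DMSs inside DMEGs; methylation classifier skipped")
  }
  if (nrow(dmegs) > 0L) {
    genes <- unique(dmegs$gene)
    feats <- t(cohort$expression$log2_expr[genes, cohort$samples$sample_id, drop = FALSE])
    evaluations$dmeg <- evaluate_feature_set(feats, labels, "dmeg_expression",
                                             classifier = clf, n_trees = n_trees,
                                             seed = config$seed)
    strata_reports$dmeg <- .run_strata(feats, labels, cohort$samples, config)
  } else {
    warning("no DMEGs; expression classifier skipped")
  }

  # --- stage: drug mapping ---
  drug_hits <- NULL
  if (!is.null(config$drug_table)) {
    tab <- if (is.character(config$drug_table)) {
      read_drug_table_file(config$drug_table)
    } else config$drug_table
    counts <- stats::aggregate(probe_id ~ gene + region, data = dms_set,
                               FUN = function(x) length(unique(x)))
    names(counts)[3L] <- "n_dms"
    drug_hits <- map_drugs(dmegs, tab,
                           dms_counts = if (nrow(dms_set) > 0L) counts)
  }

  # --- outputs ---
  write_differential_table(site_diff, file.path(out_dir, "dms_sites.tsv"))
  write_differential_table(region_diff, file.path(out_dir, "dmr_regions.tsv"))
  write_differential_table(expr_diff, file.path(out_dir, "deg_expression.tsv"))
  utils::write.table(dmgs, file.path(out_dir, "dmg_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dmegs), file.path(out_dir, "dmeg_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dms_set, file.path(out_dir, "dms_in_dmegs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_dms_bed(site_diff, cohort$annotation, file.path(out_dir, "dms_sites.bed"))
  for (nm in names(evaluations)) {
    ev <- evaluations[[nm]]
    utils::write.table(ev$roc_points, file.path(out_dir, paste0("roc_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(feature_set = ev$feature_set_name, classifier = ev$classifier,
                   auc = ev$auc, auc_p_value = ev$auc_p_value,
                   scores = as.numeric(ev$scores),
                   pca_var_explained = ev$pca$var_explained,
                   strata = lapply(strata_reports[[nm]], function(covr) {
                     lapply(covr, function(s) s[c("auc", "p", "n", "n_case", "n_control")])
                   }))
    jsonlite::write_json(report, file.path(out_dir, paste0("evaluation_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(drug_hits)) {
    utils::write.table(drug_hits$hits, file.path(out_dir, "drug_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(drug_hits$gene_summary, file.path(out_dir, "drug_gene_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  counts <- list(
    n_samples = nrow(cohort$samples),
    n_probes = length(cohort$methylation$probe_ids),
    n_genes = length(cohort$expression$gene_ids),
    dms = sum(site_diff$call != "none"),
    dmr = sum(region_diff$call != "none"),
    dmg = nrow(dmgs),
    deg = sum(expr_diff$call != "none"),
    dmeg_records = nrow(dmegs),
    dmeg_genes = length(attr(dmegs, "genes")),
    dms_in_dmegs = length(unique(dms_set$probe_id)),
    drug_hits = if (!is.null(drug_hits)) drug_hits$summary else NULL
  )
  recovery <- NULL
  if (!is.null(cohort$truth)) {
    recovery <- recovery_report(cohort$truth, dmegs)
    recovery$confusion <- as.data.frame(recovery$confusion)
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("methex")),
    seed = config$seed,
    regions = config$regions,
    thresholds = th,
    classifier = config$classifier,
    counts = counts,
    recovery = recovery,
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, site_diff = site_diff, region_diff = region_diff,
                 region_methylation = regmeth, dmgs = dmgs, expr_diff = expr_diff,
                 dmegs = dmegs, dms_in_dmegs = dms_set, evaluations = evaluations,
                 strata = strata_reports, drug_hits = drug_hits,
                 manifest = manifest))
}

.run_strata <- function(feats, labels, samples, config) {
  out <- list()
  for (covariate in config$strata) {
    if (!covariate %in% names(samples)) next
    out[[covariate]] <- suppressWarnings(
      stratified_evaluate(feats, labels, samples[[covariate]],
                          covariate_name = covariate,
                          classifier = config$classifier$name,
                          n_trees = config$classifier$n_trees,
                          seed = config$seed)
    )
  }
  out
}
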