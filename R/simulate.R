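#' Simulation configuration for a paired methylation + expression cohort
#'
#' The stated world the generator emulates: a two-group tumor cohort typed
#' on a 450K-style array (CpG betas drawn from a bimodal Beta mixture,
#' region-clustered planted methylation effects) with coupled log2
#' expression effects in the four quadrant patterns, plus clinical
#' covariates drawn independently of group.
#'
#' @param n_case,n_control Samples per group (default 40 + 40).
#' @param n_genes Genes in the universe (default 200).
#' @param cpgs_per_region Named integer vector: CpGs per gene per region
#'   (default TSS1500 = 4, TSS200 = 3, Body = 5).
#' @param n_intergenic_cpgs Unannotated background probes (default 200).
#' @param planted data.frame with columns `gene`, `regions` (";"-joined),
#'   `pattern`, `delta_beta`, `log2fc`; default = [default_planted_effects()]
#'   (20 genes, |delta beta| 0.4, |log2FC| 4).
#' @param beta_mix Baseline mixture: `list(unmeth = c(a, b), meth = c(a, b),
#'   prop_meth)`; default Beta(2,10) / Beta(10,2), 50/50.
#' @param m_noise_sd Per-cell Gaussian noise sd on the M scale (default 0.5,
#'   a typical 450K between-sample spread).
#' @param expr_baseline_mean,expr_baseline_sd Per-gene baseline log2
#'   expression distribution (default N(8, 2)).
#' @param expr_noise_sd Per-cell Gaussian noise sd on log2 expression
#'   (default 1).
#' @param seed Mandatory integer seed.
#' @param eps Beta clamping bound.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_case = 40L, n_control = 40L, n_genes = 200L,
                              cpgs_per_region = c(TSS1500 = 4L, TSS200 = 3L, Body = 5L),
                              n_intergenic_cpgs = 200L,
                              planted = default_planted_effects(n_genes),
                              beta_mix = list(unmeth = c(2, 10), meth = c(10, 2),
                                              prop_meth = 0.5),
                              m_noise_sd = 0.5,
                              expr_baseline_mean = 8, expr_baseline_sd = 2,
                              expr_noise_sd = 1,
                              seed, eps = 1e-6) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(names(cpgs_per_region) %in% REGION_LABELS),
            all(c("gene", "regions", "pattern", "delta_beta", "log2fc") %in% names(planted)))
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!all(planted$gene %in% genes)) stop("planted genes must lie in the gene universe")
  ok_sign <- with(planted, (grepl("^Hypo", pattern) == (delta_beta < 0)) &
                           (grepl("Up$", pattern) == (log2fc > 0)))
  if (!all(ok_sign)) stop("planted effect signs must match the stated pattern")
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_genes = as.integer(n_genes), genes = genes,
    cpgs_per_region = cpgs_per_region,
    n_intergenic_cpgs = as.integer(n_intergenic_cpgs),
    planted = planted, beta_mix = beta_mix, m_noise_sd = m_noise_sd,
    expr_baseline_mean = expr_baseline_mean, expr_baseline_sd = expr_baseline_sd,
    expr_noise_sd = expr_noise_sd, seed = as.integer(seed), eps = eps
  ), class = "simulation_config")
}

#' Default planted DMEG effects
#'
#' 20 planted genes with |delta beta| = 0.4 and |log2FC| = 4, planted in
#' both promoter-proximal regions (TSS1500;TSS200), with the quadrant mix
#' dominated by promoter hypomethylation with upregulation (12 HypoUp,
#' 4 HyperDown, 2 HyperUp, 2 HypoDown).
#'
#' @param n_genes Size of the gene universe the genes are drawn from.
#' @param n_planted Number of planted genes (default 20).
#' @param delta_beta,log2fc Absolute effect sizes (defaults 0.4, 4).
#' @return data.frame: `gene`, `regions`, `pattern`, `delta_beta`, `log2fc`.
#' @export
default_planted_effects <- function(n_genes = 200L, n_planted = 20L,
                                    delta_beta = 0.4, log2fc = 4) {
  if (n_planted > n_genes) stop("more planted genes than the universe holds")
  patterns <- rep(c("HypoUp", "HyperDown", "HyperUp", "HypoDown"),
                  times = pmax(0, c(n_planted - 2 * (n_planted %/% 5),
                                    n_planted %/% 5, n_planted %/% 10,
                                    n_planted %/% 5 - n_planted %/% 10)))
  patterns <- patterns[seq_len(n_planted)]
  sign_meth <- ifelse(grepl("^Hypo", patterns), -1, 1)
  sign_expr <- ifelse(grepl("Up$", patterns), 1, -1)
  data.frame(
    gene = sprintf("G%04d", seq_len(n_planted)),
    regions = rep("TSS1500;TSS200", n_planted),
    pattern = patterns,
    delta_beta = sign_meth * delta_beta,
    log2fc = sign_expr * log2fc,
    stringsAsFactors = FALSE
  )
}

#' Generate a paired methylation + expression cohort with known truth
#'
#' Baseline beta per CpG comes from the two-component Beta mixture; planted
#' (gene, region) units shift the case group's target beta by the planted
#' delta beta for every CpG in the region (the baseline for planted CpGs is
#' drawn from the mixture component compatible with the effect direction,
#' restricted to targets that stay inside (eps, 1 - eps); an infeasible
#' target errors naming the gene). Per-cell noise is Gaussian on the M
#' scale, mapped back to beta, so values always stay in (0, 1). Expression
#' is gene baseline + group effect + Gaussian noise on the log2 scale.
#' Covariates (age, menopause, race, stage) are drawn independently of
#' group. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List: `methylation` ([methylation_assay()]), `annotation`
#'   ([cpg_annotation()]), `expression` ([expression_assay()]), `samples`
#'   ([sample_sheet()]), `truth` (data.frame gene, region, pattern,
#'   delta_beta = realized noiseless region-level value, log2fc).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  eps <- config$eps
  regions <- names(config$cpgs_per_region)
  genes <- config$genes

  # --- annotation layout: per gene, k CpGs per region, plus intergenic ---
  per_gene <- sum(config$cpgs_per_region)
  n_annot <- config$n_genes * per_gene
  n_probes <- n_annot + config$n_intergenic_cpgs
  probe_id <- sprintf("cg%07d", seq_len(n_probes))
  gene_of <- c(rep(genes, each = per_gene), rep(NA_character_, config$n_intergenic_cpgs))
  region_of <- c(rep(rep(regions, times = config$cpgs_per_region), times = config$n_genes),
                 rep(NA_character_, config$n_intergenic_cpgs))
  chrom <- paste0("chr", (c(rep(seq_len(config$n_genes), each = per_gene),
                            seq_len(config$n_intergenic_cpgs)) %% 22L) + 1L)
  position <- 10000L + 137L * seq_len(n_probes)
  entries <- data.frame(probe_id = probe_id[!is.na(gene_of)],
                        gene = gene_of[!is.na(gene_of)],
                        region = region_of[!is.na(gene_of)],
                        stringsAsFactors = FALSE)
  annotation <- cpg_annotation(probe_id, chrom, position, entries)

  # --- planted effect per probe ---
  planted <- config$planted
  effect_of <- numeric(n_probes)  # case-minus-control target delta beta per CpG
  for (r in seq_len(nrow(planted))) {
    regs <- strsplit(planted$regions[r], ";", fixed = TRUE)[[1L]]
    bad <- setdiff(regs, regions)
    if (length(bad) > 0L) {
      stop(sprintf("planted gene %s uses region(s) absent from cpgs_per_region: %s",
                   planted$gene[r], paste(bad, collapse = ", ")))
    }
    hit <- which(!is.na(gene_of) & gene_of == planted$gene[r] & region_of %in% regs)
    effect_of[hit] <- planted$delta_beta[r]
  }

  # --- baseline beta per probe ---
  mix <- config$beta_mix
  draw_mode <- function(n, ab) stats::rbeta(n, ab[1L], ab[2L])
  beta0 <- numeric(n_probes)
  neutral <- effect_of == 0
  use_meth <- stats::runif(sum(neutral)) < mix$prop_meth
  beta0[neutral][use_meth] <- draw_mode(sum(use_meth), mix$meth)
  beta0[neutral][!use_meth] <- draw_mode(sum(!use_meth), mix$unmeth)
  for (j in which(!neutral)) {
    # hypo effects need a methylated baseline, hyper an unmethylated one
    ab <- if (effect_of[j] < 0) mix$meth else mix$unmeth
    ok <- FALSE
    for (try in 1:1000) {
      b <- draw_mode(1L, ab)
      if (b + effect_of[j] > eps && b + effect_of[j] < 1 - eps &&
          b > eps && b < 1 - eps) { beta0[j] <- b; ok <- TRUE; break }
    }
    if (!ok) {
      stop(sprintf("infeasible planted delta beta %.3f for gene %s: no baseline keeps the target in (eps, 1-eps)",
                   effect_of[j], gene_of[j]))
    }
  }
  beta0 <- pmin(pmax(beta0, eps), 1 - eps)
  beta1 <- beta0 + effect_of  # case-group target

  # --- sample betas: M-scale Gaussian noise around the target ---
  n_s <- config$n_case + config$n_control
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  group <- c(rep("case", config$n_case), rep("control", config$n_control))
  m_target <- cbind(
    matrix(beta_to_m(beta1), n_probes, config$n_case),
    matrix(beta_to_m(beta0), n_probes, config$n_control)
  )
  m_obs <- m_target + stats::rnorm(length(m_target), sd = config$m_noise_sd)
  beta <- m_to_beta(m_obs)
  dimnames(beta) <- list(probe_id, sample_ids)
  methylation <- methylation_assay(beta, eps = eps)

  # --- expression ---
  base_expr <- stats::rnorm(config$n_genes, config$expr_baseline_mean,
                            config$expr_baseline_sd)
  fc <- numeric(config$n_genes)
  fc[match(planted$gene, genes)] <- planted$log2fc
  expr_mean <- cbind(
    matrix(base_expr + fc, config$n_genes, config$n_case),
    matrix(base_expr, config$n_genes, config$n_control)
  )
  log2_expr <- expr_mean + stats::rnorm(length(expr_mean), sd = config$expr_noise_sd)
  dimnames(log2_expr) <- list(genes, sample_ids)
  expression <- expression_assay(log2_expr)

  # --- covariates, independent of group ---
  age <- pmin(pmax(round(stats::rnorm(n_s, 58, 10)), 30), 85)
  menopause <- ifelse(stats::runif(n_s) < ifelse(age > 50, 0.9, 0.2), "post", "pre")
  race <- sample(c("White", "Black"), n_s, replace = TRUE, prob = c(0.75, 0.25))
  stage <- sample(c("I", "II", "III_IV"), n_s, replace = TRUE,
                  prob = c(0.25, 0.5, 0.25))
  samples <- sample_sheet(sample_ids, group,
                          data.frame(age = age, menopause = menopause,
                                     race = race, stage = stage,
                                     stringsAsFactors = FALSE))

  # --- truth table: realized (noiseless) region-level delta beta ---
  truth <- do.call(rbind, lapply(seq_len(nrow(planted)), function(r) {
    regs <- strsplit(planted$regions[r], ";", fixed = TRUE)[[1L]]
    do.call(rbind, lapply(regs, function(rg) {
      j <- which(!is.na(gene_of) & gene_of == planted$gene[r] & region_of == rg)
      data.frame(gene = planted$gene[r], region = rg,
                 pattern = planted$pattern[r],
                 delta_beta = region_beta(beta1[j]) - region_beta(beta0[j]),
                 log2fc = planted$log2fc[r], stringsAsFactors = FALSE)
    }))
  }))
  rownames(truth) <- NULL

  list(methylation = methylation, annotation = annotation,
       expression = expression, samples = samples, truth = truth)
}

#' Write a generated cohort to disk in the pipeline's input formats
#'
#' Emits beta.tsv, annotation.tsv, expression.tsv, samples.tsv and
#' truth.tsv under `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named vector of the five file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_file(cohort$methylation$beta, paths["beta"], id_col = "probe_id")
  ent <- cohort$annotation$entries
  joined <- vapply(split(ent, ent$probe_id), function(d) {
    c(paste(d$gene, collapse = ";"), paste(d$region, collapse = ";"))
  }, character(2))
  pr <- cohort$annotation$probes
  idx <- match(pr$probe_id, colnames(joined))
  annot_df <- data.frame(
    probe_id = pr$probe_id, chrom = pr$chrom, pos = pr$position,
    gene_symbols = ifelse(is.na(idx), "", joined[1L, idx]),
    region_labels = ifelse(is.na(idx), "", joined[2L, idx]),
    stringsAsFactors = FALSE
  )
  utils::write.table(annot_df, paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_file(cohort$expression$log2_expr, paths["expression"], id_col = "gene_id")
  utils::write.table(as.data.frame(cohort$samples), paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Compare called DMEGs with the planted truth
#'
#' Matches on (gene, region). Sensitivity = matched / planted; precision =
#' matched / called (NA when nothing was called); the confusion table
#' crosses planted patterns with called patterns on the matched pairs.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param called A `dmeg_table` from [build_dmeg_table()].
#' @return List: `sensitivity`, `precision`, `n_truth`, `n_called`,
#'   `n_matched`, `confusion` (planted x called pattern table),
#'   `pattern_agreement` (fraction of matched pairs with identical pattern).
#' @export
recovery_report <- function(truth, called) {
  key_t <- paste(truth$gene, truth$region)
  key_c <- paste(called$gene, called$region)
  matched <- intersect(key_t, key_c)
  n_matched <- length(matched)
  it <- match(matched, key_t)
  ic <- match(matched, key_c)
  patterns <- c("HypoUp", "HypoDown", "HyperUp", "HyperDown")
  confusion <- table(
    planted = factor(truth$pattern[it], levels = patterns),
    called = factor(called$pattern[ic], levels = patterns)
  )
  list(
    sensitivity = if (nrow(truth) > 0L) n_matched / nrow(truth) else NA_real_,
    precision = if (nrow(called) > 0L) n_matched / nrow(called) else NA_real_,
    n_truth = nrow(truth), n_called = nrow(called), n_matched = n_matched,
    confusion = confusion,
    pattern_agreement = if (n_matched > 0L) {
      mean(truth$pattern[it] == called$pattern[ic])
    } else NA_real_
  )
}
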