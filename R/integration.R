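#' Quadrant classification of a (gene, region) methylation/expression pair
#'
#' The four coupled patterns, all cutoffs strict:
#' \itemize{
#'   \item HypoUp:    meth adj_p < 0.05 & delta beta < -0.2; expr adj_p < 0.05 & logFC > 2
#'   \item HypoDown:  meth adj_p < 0.05 & delta beta < -0.2; expr adj_p < 0.05 & logFC < -2
#'   \item HyperUp:   meth adj_p < 0.05 & delta beta > 0.2;  expr adj_p < 0.05 & logFC > 2
#'   \item HyperDown: meth adj_p < 0.05 & delta beta > 0.2;  expr adj_p < 0.05 & logFC < -2
#' }
#' Returns "none" if either axis fails its significance or magnitude cutoff.
#'
#' @param delta_beta Region-level delta beta (case minus control).
#' @param meth_adj_p BH-adjusted methylation p-value.
#' @param log2fc Log2 fold change of expression.
#' @param expr_adj_p BH-adjusted expression p-value.
#' @param p_cut,beta_cut,fc_cut Thresholds (defaults 0.05, 0.2, 2).
#' @return Character vector in `{HypoUp, HypoDown, HyperUp, HyperDown, none}`.
#' @export
classify_dmeg <- function(delta_beta, meth_adj_p, log2fc, expr_adj_p,
                          p_cut = 0.05, beta_cut = 0.2, fc_cut = 2) {
  meth_dir <- .axis_call(meth_adj_p, delta_beta, p_cut, beta_cut, c("Hyper", "Hypo"))
  expr_dir <- .axis_call(expr_adj_p, log2fc, p_cut, fc_cut, c("Up", "Down"))
  out <- rep("none", length(meth_dir))
  both <- meth_dir != "none" & expr_dir != "none"
  out[both] <- paste0(meth_dir[both], expr_dir[both])
  out
}

.axis_call <- function(adj_p, effect, p_cut, effect_cut, labels) {
  call <- rep("none", length(adj_p))
  sig <- !is.na(adj_p) & !is.na(effect) & adj_p < p_cut
  call[sig & effect > effect_cut] <- labels[1L]
  call[sig & effect < -effect_cut] <- labels[2L]
  call
}

#' DMEG table: intersection of DMGs and DEGs with quadrant patterns
#'
#' Joins the region-level methylation table to the expression table on gene
#' symbol and classifies every (gene, region) pair into one of the four
#' quadrants. A record is kept only if both axes pass (the pattern is not
#' "none") — i.e. the gene is a DMG in that region AND a DEG. A gene may
#' carry different patterns in different regions; all records are kept.
#'
#' @param region_diff Region-level [diff_methylation()] output.
#' @param expr_diff [diff_expression()] output.
#' @param p_cut,beta_cut,fc_cut Thresholds (defaults 0.05, 0.2, 2).
#' @return A `dmeg_table`: data.frame with `gene`, `region`, `delta_beta`,
#'   `log2fc`, `meth_adj_p`, `expr_adj_p`, `pattern`; attributes `genes`
#'   (deduplicated gene vector) and `region_multiplicity` (how many genes
#'   appear in exactly 1, 2, ... of the analysed regions).
#' @export
build_dmeg_table <- function(region_diff, expr_diff,
                             p_cut = 0.05, beta_cut = 0.2, fc_cut = 2) {
  stopifnot(all(c("gene", "region", "effect", "adj_p") %in% names(region_diff)),
            all(c("feature", "effect", "adj_p") %in% names(expr_diff)))
  idx <- match(region_diff$gene, expr_diff$feature)
  joined <- data.frame(
    gene = region_diff$gene,
    region = region_diff$region,
    delta_beta = region_diff$effect,
    log2fc = expr_diff$effect[idx],
    meth_adj_p = region_diff$adj_p,
    expr_adj_p = expr_diff$adj_p[idx],
    stringsAsFactors = FALSE
  )
  joined <- joined[!is.na(idx), , drop = FALSE]
  joined$pattern <- classify_dmeg(joined$delta_beta, joined$meth_adj_p,
                                  joined$log2fc, joined$expr_adj_p,
                                  p_cut, beta_cut, fc_cut)
  out <- joined[joined$pattern != "none", , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("empty DMEG table: no gene passes both axes")
  genes <- sort(unique(out$gene))
  mult <- table(factor(tapply(out$region, out$gene, function(r) length(unique(r))),
                       levels = seq_along(unique(region_diff$region))))
  attr(out, "genes") <- genes
  attr(out, "region_multiplicity") <- as.integer(mult)
  class(out) <- c("dmeg_table", "data.frame")
  out
}

#' Pattern proportions per region
#'
#' Fraction of each quadrant pattern among the DMEG records of each region.
#'
#' @param records A `dmeg_table` (or any data.frame with `region`, `pattern`).
#' @return data.frame: `region`, `pattern`, `n`, `proportion` (proportions
#'   sum to 1 within each region).
#' @export
pattern_proportions <- function(records) {
  if (nrow(records) == 0L) stop("no DMEG records")
  patterns <- c("HypoUp", "HypoDown", "HyperUp", "HyperDown")
  tab <- table(records$region, factor(records$pattern, levels = patterns))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("region", "pattern", "n")
  totals <- rowSums(tab)[out$region]
  out$proportion <- out$n / as.numeric(totals)
  out[order(out$region, match(out$pattern, patterns)), , drop = FALSE]
}

#' DMSs located inside DMEGs
#'
#' Extracts the called sites whose probes are annotated to a DMEG's gene in
#' one of the requested regions — the site-level feature set used for the
#' methylation classifier.
#'
#' @param site_diff Site-level [diff_methylation()] output.
#' @param dmegs A `dmeg_table`.
#' @param annotation A [cpg_annotation()].
#' @param regions Regions the sites may fall in (default TSS1500 + TSS200,
#'   the promoter-proximal pair used for classification).
#' @return data.frame: `probe_id`, `gene`, `region`, `effect`, `adj_p`, `call`.
#' @export
dms_in_dmegs <- function(site_diff, dmegs, annotation,
                         regions = c("TSS1500", "TSS200")) {
  called <- site_diff[site_diff$call %in% c("hyper", "hypo"), , drop = FALSE]
  ent <- annotation$entries
  ent <- ent[ent$gene %in% unique(dmegs$gene) & ent$region %in% regions, , drop = FALSE]
  hit <- merge(called, ent, by.x = "feature", by.y = "probe_id")
  if (nrow(hit) == 0L) {
    return(data.frame(probe_id = character(0), gene = character(0),
                      region = character(0), effect = numeric(0),
                      adj_p = numeric(0), call = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(probe_id = hit$feature, gene = hit$gene, region = hit$region,
                    effect = hit$effect, adj_p = hit$adj_p, call = hit$call,
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$region, out$probe_id), , drop = FALSE]
}
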