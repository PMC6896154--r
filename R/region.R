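#' Region-level beta from CpG-level betas
#'
#' Aggregates the beta values of the k CpGs in one (gene, region) unit for
#' one sample as \eqn{2^{(\sum_i \log_2 \beta_i)/k}} — the geometric mean.
#'
#' @param betas Numeric vector of CpG betas, all strictly in (0, 1).
#'   NA entries are excluded; all-NA input returns NA.
#' @return The aggregated region beta (scalar).
#' @examples
#' region_beta(c(0.5, 0.125))  # 0.25
#' @export
region_beta <- function(betas) {
  if (length(betas) == 0L) stop("region_beta: empty beta vector")
  betas <- betas[!is.na(betas)]
  if (length(betas) == 0L) return(NA_real_)
  if (any(betas <= 0 | betas >= 1)) stop("region_beta: betas must lie strictly in (0,1)")
  2^(mean(log2(betas)))
}

#' Aggregate CpG-level methylation to (gene, region) level
#'
#' For every (gene, region) pair with at least one annotated probe among the
#' requested `regions`, computes the per-sample geometric-mean beta over the
#' pair's probes, plus its M-value transform. A probe annotated to several
#' pairs contributes to each; intergenic probes contribute to none.
#'
#' @param assay A [methylation_assay()].
#' @param annotation A [cpg_annotation()].
#' @param regions Region labels to aggregate (default
#'   `r paste(DEFAULT_REGIONS, collapse = ", ")`).
#' @return A `region_methylation` object: `keys` (data.frame gene, region,
#'   k), `beta_region`, `m_region` (matrices keyed "gene|region"),
#'   `sample_ids`.
#' @export
aggregate_regions <- function(assay, annotation, regions = DEFAULT_REGIONS) {
  stopifnot(inherits(assay, "methylation_assay"), inherits(annotation, "cpg_annotation"))
  bad <- setdiff(regions, REGION_LABELS)
  if (length(bad) > 0L) stop("unknown region label(s): ", paste(bad, collapse = ", "))

  ent <- annotation$entries
  ent <- ent[ent$region %in% regions & ent$probe_id %in% assay$probe_ids, , drop = FALSE]
  if (nrow(ent) == 0L) {
    warning("no probe maps to any requested region; empty result")
    empty <- matrix(numeric(0), nrow = 0, ncol = length(assay$sample_ids),
                    dimnames = list(NULL, assay$sample_ids))
    return(structure(list(
      keys = data.frame(gene = character(0), region = character(0), k = integer(0)),
      beta_region = empty, m_region = empty, sample_ids = assay$sample_ids
    ), class = "region_methylation"))
  }

  key <- paste(ent$gene, ent$region, sep = "|")
  log2beta <- log2(assay$beta)
  groups <- split(match(ent$probe_id, assay$probe_ids), key)
  # geometric mean per key: 2^(column means of log2 beta over member probes),
  # NA cells excluded pairwise
  agg <- t(vapply(groups, function(idx) {
    sub <- log2beta[idx, , drop = FALSE]
    2^(colMeans(sub, na.rm = TRUE))
  }, numeric(ncol(assay$beta))))
  agg[is.nan(agg)] <- NA_real_
  colnames(agg) <- assay$sample_ids

  keys <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  keys <- data.frame(gene = keys[, 1L], region = keys[, 2L],
                     k = lengths(groups), stringsAsFactors = FALSE)
  ord <- order(keys$gene, match(keys$region, REGION_LABELS))
  keys <- keys[ord, , drop = FALSE]; rownames(keys) <- NULL
  agg <- agg[ord, , drop = FALSE]

  m_region <- agg
  ok <- !is.na(agg)
  m_region[ok] <- beta_to_m(agg[ok])

  structure(list(keys = keys, beta_region = agg, m_region = m_region,
                 sample_ids = assay$sample_ids),
            class = "region_methylation")
}

#' @export
print.region_methylation <- function(x, ...) {
  cat(sprintf("region_methylation: %d (gene, region) units x %d samples [regions: %s]\n",
              nrow(x$keys), length(x$sample_ids),
              paste(unique(x$keys$region), collapse = ", ")))
  invisible(x)
}

#' Case-minus-control difference in mean beta
#'
#' \eqn{\Delta\beta} = case-group mean minus control-group mean, on the beta
#' scale, at site or region level.
#'
#' @param beta_case_mean,beta_control_mean Finite group means (vectorized).
#' @return `beta_case_mean - beta_control_mean`.
#' @export
delta_beta <- function(beta_case_mean, beta_control_mean) {
  beta_case_mean - beta_control_mean
}

#' Write a region_methylation object as TSV
#'
#' Columns: gene, region, k, then one beta column per sample.
#'
#' @param rm A `region_methylation` object.
#' @param path Output path.
#' @export
write_region_methylation <- function(rm, path) {
  df <- cbind(rm$keys, as.data.frame(rm$beta_region, check.names = FALSE))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
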