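#' Region label vocabulary
#'
#' The fixed Illumina-450K-manifest relation-to-gene vocabulary used
#' throughout. Probes with no gene annotation are intergenic.
#' @export
REGION_LABELS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")

#' Default regions analysed
#'
#' The promoter-proximal and gene-body regions most informative for
#' methylation-expression coupling; the remaining labels stay selectable.
#' @export
DEFAULT_REGIONS <- c("TSS1500", "TSS200", "Body")

#' Construct a methylation assay
#'
#' A CpG-by-sample beta-value container. Betas are clamped into
#' `[eps, 1 - eps]` so the logit2 (M-value) transform is always finite.
#'
#' @param beta Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are used as probe/sample ids when `probe_ids`/`sample_ids`
#'   are not given.
#' @param probe_ids,sample_ids Character vectors of unique ids.
#' @param source `"direct_beta"` if read from a beta matrix,
#'   `"from_intensities"` if derived via [compute_beta()].
#' @param eps Clamping bound passed to [clamp_beta()].
#' @return A `methylation_assay` object (list with `beta`, `probe_ids`,
#'   `sample_ids`, `source`, `n_clamped`).
#' @export
methylation_assay <- function(beta, probe_ids = rownames(beta),
                              sample_ids = colnames(beta),
                              source = c("direct_beta", "from_intensities"),
                              eps = 1e-6) {
  source <- match.arg(source)
  beta <- as.matrix(beta)
  .check_ids(probe_ids, nrow(beta), "probe")
  .check_ids(sample_ids, ncol(beta), "sample")
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("beta values must lie in [0,1]")
  }
  beta <- clamp_beta(beta, eps = eps, quiet = TRUE)
  n_clamped <- attr(beta, "n_clamped")
  attr(beta, "n_clamped") <- NULL
  dimnames(beta) <- list(probe_ids, sample_ids)
  structure(
    list(beta = beta, probe_ids = probe_ids, sample_ids = sample_ids,
         source = source, n_clamped = n_clamped),
    class = "methylation_assay"
  )
}

#' @export
print.methylation_assay <- function(x, ...) {
  cat(sprintf("methylation_assay: %d probes x %d samples (source: %s, %d cells clamped)\n",
              length(x$probe_ids), length(x$sample_ids), x$source, x$n_clamped))
  invisible(x)
}

#' Construct a CpG annotation table
#'
#' Maps each probe to zero or more (gene, region) pairs. A probe with no
#' pairs is intergenic. Multi-annotations arise from the manifest's
#' semicolon-joined gene/region columns; duplicated (probe, gene, region)
#' triples are collapsed.
#'
#' @param probe_id,chrom,position Per-probe vectors (position 1-based).
#' @param entries data.frame with columns `probe_id`, `gene`, `region` —
#'   one row per exploded (probe, gene, region) pair.
#' @return A `cpg_annotation` object: `probes` (data.frame: probe_id, chrom,
#'   position, intergenic) and `entries`.
#' @export
cpg_annotation <- function(probe_id, chrom, position, entries) {
  if (anyDuplicated(probe_id)) stop("duplicate probe ids in annotation")
  stopifnot(is.data.frame(entries),
            all(c("probe_id", "gene", "region") %in% names(entries)))
  bad_region <- setdiff(unique(entries$region), REGION_LABELS)
  if (length(bad_region) > 0L) {
    stop("unparseable region label(s): ", paste(bad_region, collapse = ", "))
  }
  if (!all(entries$probe_id %in% probe_id)) {
    stop("annotation entries reference unknown probes")
  }
  entries <- unique(entries[, c("probe_id", "gene", "region")])
  rownames(entries) <- NULL
  probes <- data.frame(
    probe_id = probe_id, chrom = chrom, position = as.integer(position),
    intergenic = !(probe_id %in% entries$probe_id),
    stringsAsFactors = FALSE
  )
  structure(list(probes = probes, entries = entries), class = "cpg_annotation")
}

#' @export
print.cpg_annotation <- function(x, ...) {
  cat(sprintf("cpg_annotation: %d probes (%d intergenic), %d (gene, region) entries\n",
              nrow(x$probes), sum(x$probes$intergenic), nrow(x$entries)))
  invisible(x)
}

#' Construct an expression assay
#'
#' Gene-by-sample matrix of log2-transformed expression values.
#'
#' @param log2_expr Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids Character vectors of unique ids.
#' @return An `expression_assay` object.
#' @export
expression_assay <- function(log2_expr, gene_ids = rownames(log2_expr),
                             sample_ids = colnames(log2_expr)) {
  log2_expr <- as.matrix(log2_expr)
  .check_ids(gene_ids, nrow(log2_expr), "gene")
  .check_ids(sample_ids, ncol(log2_expr), "sample")
  if (any(!is.finite(log2_expr))) stop("log2 expression must be finite (no NA/Inf)")
  dimnames(log2_expr) <- list(gene_ids, sample_ids)
  structure(
    list(log2_expr = log2_expr, gene_ids = gene_ids, sample_ids = sample_ids),
    class = "expression_assay"
  )
}

#' @export
print.expression_assay <- function(x, ...) {
  cat(sprintf("expression_assay: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Construct a sample sheet
#'
#' Group labels and optional clinical covariates per sample. `group` is
#' normalized to a factor with levels `c("control", "case")`.
#'
#' @param sample_id Unique sample ids.
#' @param group Character/factor with exactly the values "case"/"control".
#' @param covariates Optional data.frame of per-sample covariates
#'   (e.g. `age`, `menopause`, `race`, `stage`).
#' @return A `sample_sheet` object (data.frame under the hood).
#' @export
sample_sheet <- function(sample_id, group, covariates = NULL) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad) > 0L) {
    stop("group must be 'case' or 'control'; found: ", paste(bad, collapse = ", "))
  }
  df <- data.frame(sample_id = as.character(sample_id),
                   group = factor(group, levels = c("control", "case")),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(sample_id))
    df <- cbind(df, covariates)
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct a drug-target table
#'
#' Local snapshot of drug-target interactions (DrugBank-like dialect):
#' one row per (drug, target gene). Unknown approval statuses are bucketed
#' into "other" with a warning. Target symbols are harmonized to upper case.
#'
#' @param drug_id,drug_name,approval_status,target_gene_symbol Equal-length
#'   vectors; `approval_status` in `{approved, experimental, other}`.
#' @return A `drug_target_table` (data.frame).
#' @export
drug_target_table <- function(drug_id, drug_name, approval_status,
                              target_gene_symbol) {
  approval_status <- as.character(approval_status)
  unknown <- !(approval_status %in% c("approved", "experimental", "other"))
  if (any(unknown)) {
    warning(sprintf("%d unknown approval statuses bucketed into 'other'", sum(unknown)))
    approval_status[unknown] <- "other"
  }
  df <- data.frame(
    drug_id = as.character(drug_id),
    drug_name = as.character(drug_name),
    approval_status = approval_status,
    target_gene_symbol = toupper(as.character(target_gene_symbol)),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) stop("empty drug-target table")
  dup <- duplicated(df[, c("drug_id", "target_gene_symbol")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_target_table", "data.frame")
  df
}

.check_ids <- function(ids, n, what) {
  if (is.null(ids)) stop(sprintf("%s ids are required (set dimnames or pass explicitly)", what))
  if (length(ids) != n) stop(sprintf("%s ids do not match matrix dimension", what))
  if (anyDuplicated(ids)) stop(sprintf("duplicate %s ids", what))
  invisible(TRUE)
}
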