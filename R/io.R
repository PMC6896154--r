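#' Read a feature-by-sample matrix from TSV/CSV
#'
#' First column is the feature id, header row holds sample ids.
#'
#' @param path File path.
#' @param sep Field separator ("\t" default; "," for CSV).
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_file <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("matrix file needs a feature-id column plus >=1 sample column: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix_file()]; round-trips values at full precision.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @export
write_matrix_file <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Illumina-manifest-style CpG annotation TSV
#'
#' Expected columns: `probe_id`, `chrom`, `pos`, `gene_symbols`
#' (";"-joined) and `region_labels` (";"-joined, positionally paired with
#' the gene symbols). Empty gene field = intergenic probe. Exploded
#' duplicate (gene, region) pairs are kept once.
#'
#' @param path File path.
#' @return A [cpg_annotation()] object.
#' @export
read_annotation_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("probe_id", "chrom", "pos", "gene_symbols", "region_labels")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("annotation file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  entries <- .explode_annotations(df$probe_id, df$gene_symbols, df$region_labels)
  cpg_annotation(df$probe_id, df$chrom, as.integer(df$pos), entries)
}

# Split ";"-joined gene/region columns into one row per (probe, gene, region).
.explode_annotations <- function(probe_id, gene_symbols, region_labels) {
  gene_symbols[is.na(gene_symbols)] <- ""
  region_labels[is.na(region_labels)] <- ""
  genes <- strsplit(gene_symbols, ";", fixed = TRUE)
  regions <- strsplit(region_labels, ";", fixed = TRUE)
  ng <- lengths(genes)
  nr <- lengths(regions)
  if (any(ng != nr)) {
    bad <- which(ng != nr)[1L]
    stop(sprintf("probe %s: %d gene symbols but %d region labels (must pair positionally)",
                 probe_id[bad], ng[bad], nr[bad]))
  }
  out <- data.frame(
    probe_id = rep(probe_id, ng),
    gene = unlist(genes, use.names = FALSE),
    region = unlist(regions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out <- out[out$gene != "", , drop = FALSE]
  unique(out)
}

#' Read a sample sheet TSV
#'
#' Columns: `sample_id`, `group` (case/control), plus optional covariate
#' columns (e.g. age, menopause, race, stage).
#'
#' @param path File path.
#' @return A [sample_sheet()] object.
#' @export
read_sample_sheet_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample sheet missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  cov <- df[, setdiff(names(df), need), drop = FALSE]
  sample_sheet(df$sample_id, df$group, if (ncol(cov) > 0L) cov else NULL)
}

#' Read a drug-target table TSV
#'
#' Columns: `drug_id`, `drug_name`, `status`, `target_gene`.
#'
#' @param path File path.
#' @return A [drug_target_table()] object.
#' @export
read_drug_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("drug_id", "drug_name", "status", "target_gene")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("drug table missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  drug_target_table(df$drug_id, df$drug_name, df$status, df$target_gene)
}

#' Read and align all pipeline inputs
#'
#' Loads the beta matrix (or intensity pair), annotation, expression matrix
#' and sample sheet, then restricts every assay to the samples present in
#' all of them, reporting the dropped samples.
#'
#' @param beta_path CpG-by-sample beta matrix TSV (mutually exclusive with
#'   `meth_intensity_path`/`unmeth_intensity_path`).
#' @param annotation_path Annotation TSV ([read_annotation_file()] dialect).
#' @param expression_path Gene-by-sample log2 expression TSV.
#' @param sample_sheet_path Sample sheet TSV.
#' @param meth_intensity_path,unmeth_intensity_path Optional raw intensity
#'   matrices; betas derived via [compute_beta()].
#' @param sep Field separator for the matrix files.
#' @return List with `methylation`, `annotation`, `expression`, `samples`
#'   and `dropped_samples` (character vector).
#' @export
read_assays <- function(beta_path = NULL, annotation_path, expression_path,
                        sample_sheet_path, meth_intensity_path = NULL,
                        unmeth_intensity_path = NULL, sep = "\t") {
  if (is.null(beta_path)) {
    if (is.null(meth_intensity_path) || is.null(unmeth_intensity_path)) {
      stop("provide either beta_path or both intensity paths")
    }
    M <- read_matrix_file(meth_intensity_path, sep)
    U <- read_matrix_file(unmeth_intensity_path, sep)
    if (!identical(dimnames(M), dimnames(U))) {
      stop("methylated/unmethylated intensity matrices must have identical dimnames")
    }
    beta <- compute_beta(M, U)
    dim(beta) <- dim(M); dimnames(beta) <- dimnames(M)
    source <- "from_intensities"
  } else {
    beta <- read_matrix_file(beta_path, sep)
    source <- "direct_beta"
  }
  annot <- read_annotation_file(annotation_path)
  expr <- read_matrix_file(expression_path, sep)
  sheet <- read_sample_sheet_file(sample_sheet_path)

  shared <- Reduce(intersect, list(colnames(beta), colnames(expr), sheet$sample_id))
  if (length(shared) == 0L) stop("zero overlapping samples across inputs")
  all_seen <- unique(c(colnames(beta), colnames(expr), sheet$sample_id))
  dropped <- setdiff(all_seen, shared)
  if (length(dropped) > 0L) {
    message(sprintf("read_assays: %d samples dropped (absent from some input): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  sheet <- sheet[match(shared, sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL

  list(
    methylation = methylation_assay(beta[, shared, drop = FALSE], source = source),
    annotation = annot,
    expression = expression_assay(expr[, shared, drop = FALSE]),
    samples = sheet,
    dropped_samples = dropped
  )
}

#' Write a differential table as TSV
#'
#' @param tab A data.frame from [diff_methylation()]/[diff_expression()].
#' @param path Output path.
#' @export
write_differential_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export called DMSs as 4-column BED
#'
#' 0-based half-open intervals, name = probe id.
#'
#' @param site_table Site-level differential table with a `call` column.
#' @param annotation A [cpg_annotation()] object (for chrom/pos lookup).
#' @param path Output path.
#' @export
write_dms_bed <- function(site_table, annotation, path) {
  dms <- site_table[site_table$call %in% c("hyper", "hypo"), , drop = FALSE]
  idx <- match(dms$feature, annotation$probes$probe_id)
  if (anyNA(idx)) stop("DMS probes missing from annotation")
  bed <- data.frame(
    chrom = annotation$probes$chrom[idx],
    start = annotation$probes$position[idx] - 1L,
    end = annotation$probes$position[idx],
    name = dms$feature,
    stringsAsFactors = FALSE
  )
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
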