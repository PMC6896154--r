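#' Cross-reference upregulated DMEGs against a drug-target table
#'
#' Joins the DMEG records whose pattern is HypoUp or HyperUp (upregulated
#' only) to a local drug-target snapshot on harmonized (upper-case) gene
#' symbol. One hit per (gene, drug) pair; a gene's regions and patterns are
#' collapsed into the hit.
#'
#' @param dmegs A `dmeg_table` from [build_dmeg_table()].
#' @param drug_table A [drug_target_table()].
#' @param dms_counts Optional data.frame (`gene`, `region`, `n_dms`) from
#'   site-level calls, merged into the per-gene summary.
#' @return List: `hits` (data.frame gene, regions, patterns, drug_id,
#'   drug_name, approval_status), `gene_summary` (Table-3-style: gene,
#'   regions, patterns, dms, n_drugs, example_drugs = first three
#'   alphabetically) and `summary` (n_drugs, n_approved, n_genes — unique
#'   drugs deduplicated across genes).
#' @export
map_drugs <- function(dmegs, drug_table, dms_counts = NULL) {
  stopifnot(inherits(drug_table, "drug_target_table"))
  up <- dmegs[dmegs$pattern %in% c("HypoUp", "HyperUp"), , drop = FALSE]
  per_gene <- if (nrow(up) > 0L) {
    sp <- split(up, toupper(up$gene))
    data.frame(
      gene = names(sp),
      regions = vapply(sp, function(d) paste(d$region, collapse = ";"), character(1)),
      patterns = vapply(sp, function(d) paste(d$pattern, collapse = ";"), character(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(gene = character(0), regions = character(0), patterns = character(0),
               stringsAsFactors = FALSE)
  }
  hits <- merge(per_gene, drug_table, by.x = "gene", by.y = "target_gene_symbol")
  hits <- hits[order(hits$gene, hits$drug_name, hits$drug_id), , drop = FALSE]
  rownames(hits) <- NULL

  gene_summary <- if (nrow(hits) > 0L) {
    sp <- split(hits, hits$gene)
    data.frame(
      gene = names(sp),
      regions = vapply(sp, function(d) d$regions[1L], character(1)),
      patterns = vapply(sp, function(d) d$patterns[1L], character(1)),
      n_drugs = vapply(sp, nrow, integer(1)),
      example_drugs = vapply(sp, function(d) {
        paste(utils::head(sort(unique(d$drug_name)), 3L), collapse = ", ")
      }, character(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(gene = character(0), regions = character(0), patterns = character(0),
               n_drugs = integer(0), example_drugs = character(0),
               stringsAsFactors = FALSE)
  }
  if (!is.null(dms_counts) && nrow(gene_summary) > 0L) {
    agg <- stats::aggregate(n_dms ~ gene, data = dms_counts, FUN = sum)
    agg$gene <- toupper(agg$gene)
    gene_summary$dms <- agg$n_dms[match(gene_summary$gene, agg$gene)]
    gene_summary$dms[is.na(gene_summary$dms)] <- 0L
  }

  list(
    hits = hits,
    gene_summary = gene_summary,
    summary = list(
      n_hits = nrow(hits),
      n_drugs = length(unique(hits$drug_id)),
      n_approved = length(unique(hits$drug_id[hits$approval_status == "approved"])),
      n_genes = length(unique(hits$gene))
    )
  )
}

#' Allocate genes to user-supplied categories
#'
#' Assigns each gene a category from a gene-to-category map (e.g. Receptors /
#' Functional Proteins / Structural Proteins); genes absent from the map are
#' labeled "unassigned". The map must assign each gene at most one category.
#'
#' @param genes Character vector of gene symbols.
#' @param category_map data.frame with columns `gene`, `category` (or a path
#'   to a two-column TSV with that header).
#' @return data.frame: `gene`, `category`.
#' @export
categorize_genes <- function(genes, category_map) {
  if (is.character(category_map) && length(category_map) == 1L) {
    category_map <- utils::read.table(category_map, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE, quote = "")
  }
  stopifnot(all(c("gene", "category") %in% names(category_map)))
  category_map$gene <- toupper(category_map$gene)
  if (anyDuplicated(category_map$gene)) {
    dup <- unique(category_map$gene[duplicated(category_map$gene)])
    stop("gene(s) mapped to more than one category: ", paste(dup, collapse = ", "))
  }
  g <- toupper(genes)
  cat_ <- category_map$category[match(g, category_map$gene)]
  cat_[is.na(cat_)] <- "unassigned"
  data.frame(gene = genes, category = cat_, stringsAsFactors = FALSE)
}
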