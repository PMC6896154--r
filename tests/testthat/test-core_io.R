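test_that("compute_beta matches the analytic cases and rejects bad input", {
  expect_identical(compute_beta(100, 0), 0.5)
  expect_identical(compute_beta(0, 500), 0)
  expect_identical(compute_beta(900, 0), 0.9)
  expect_error(compute_beta(-1, 5), "negative")
  expect_error(compute_beta(1, c(2, 3)), "same length")

  m <- matrix(c(100, 0, 900, 300), 2)
  u <- matrix(c(0, 500, 0, 100), 2)
  expect_equal(compute_beta(m, u), m / (m + u + 100))
})

test_that("compute_beta is monotone in M and U and always < 1", {
  M <- seq(0, 5000, by = 250)
  expect_true(all(diff(compute_beta(M, rep(200, length(M)))) > 0))
  U <- seq(0, 5000, by = 250)
  expect_true(all(diff(compute_beta(rep(200, length(U)), U)) < 0))
  set.seed(11)
  b <- compute_beta(runif(500, 0, 1e6), runif(500, 0, 1e6))
  expect_true(all(b < 1 & b >= 0))
})

test_that("beta/M conversions: fixed points, round trip, symmetry, monotonicity", {
  expect_identical(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  for (x in c(0.1, 0.37, 0.92)) expect_equal(m_to_beta(beta_to_m(x)), x)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_equal(beta_to_m(1 - b), -beta_to_m(b))
  expect_error(beta_to_m(0), "strictly")
  expect_error(beta_to_m(1), "strictly")
})

test_that("clamp_beta reports clamped cells and enables conversion", {
  x <- c(0, 0.5, 1, NA)
  out <- suppressMessages(clamp_beta(x))
  expect_equal(attr(out, "n_clamped"), 2)
  expect_true(all(is.finite(beta_to_m(out[1:3]))))
  expect_equal(out[2], 0.5)
})

test_that("constructors enforce id and value invariants", {
  b <- matrix(0.5, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(methylation_assay(b), "duplicate probe")
  b2 <- matrix(c(0.5, 1.2, 0.3, 0.4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(methylation_assay(b2), "\\[0,1\\]")
  e <- matrix(c(1, NA, 2, 3), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_assay(e), "finite")
  expect_error(sample_sheet(c("s1", "s2"), c("case", "tumour")), "group")
  expect_error(
    cpg_annotation("cg1", "chr1", 1L,
                   data.frame(probe_id = "cg1", gene = "G", region = "Promoter")),
    "region label"
  )
})

test_that("annotation explosion pairs positionally and deduplicates", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "probe_id\tchrom\tpos\tgene_symbols\tregion_labels",
    "cg1\tchr1\t100\tGENEA;GENEA;GENEB\tTSS200;Body;TSS1500",
    "cg2\tchr1\t200\tGENEA;GENEA\tTSS200;TSS200",
    "cg3\tchr2\t300\t\t"
  ), file.path(dir, "annot.tsv"))
  ann <- read_annotation_file(file.path(dir, "annot.tsv"))
  e1 <- ann$entries[ann$entries$probe_id == "cg1", ]
  expect_equal(nrow(e1), 3L)
  expect_setequal(paste(e1$gene, e1$region), c("GENEA TSS200", "GENEA Body", "GENEB TSS1500"))
  # duplicated exploded pair kept once
  expect_equal(nrow(ann$entries[ann$entries$probe_id == "cg2", ]), 1L)
  # empty gene field => intergenic
  expect_true(ann$probes$intergenic[ann$probes$probe_id == "cg3"])
  expect_false(any(ann$probes$intergenic[ann$probes$probe_id %in% c("cg1", "cg2")]))
})

test_that("matrix writer/reader round-trips to 1e-12", {
  dir <- withr::local_tempdir()
  set.seed(42)
  m <- matrix(runif(60), 10, dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:6)))
  p <- file.path(dir, "m.tsv")
  write_matrix_file(m, p)
  m2 <- read_matrix_file(p)
  expect_equal(m2, m, tolerance = 1e-12)
  expect_identical(dimnames(m2), dimnames(m))
})

test_that("read_assays restricts to the shared samples and logs drops", {
  dir <- withr::local_tempdir()
  beta <- matrix(runif(8, 0.2, 0.8), 2,
                 dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3", "sm_only")))
  write_matrix_file(beta, file.path(dir, "beta.tsv"), id_col = "probe_id")
  expr <- matrix(rnorm(6, 8), 2, dimnames = list(c("GENEA", "GENEB"), c("s1", "s2", "s3")))
  write_matrix_file(expr, file.path(dir, "expr.tsv"), id_col = "gene_id")
  writeLines(c("probe_id\tchrom\tpos\tgene_symbols\tregion_labels",
               "cg1\tchr1\t100\tGENEA\tTSS200",
               "cg2\tchr1\t200\tGENEB\tBody"),
             file.path(dir, "annot.tsv"))
  writeLines(c("sample_id\tgroup", "s1\tcase", "s2\tcase", "s3\tcontrol"),
             file.path(dir, "samples.tsv"))

  expect_message(
    inputs <- read_assays(file.path(dir, "beta.tsv"), file.path(dir, "annot.tsv"),
                          file.path(dir, "expr.tsv"), file.path(dir, "samples.tsv")),
    "sm_only"
  )
  expect_equal(inputs$methylation$sample_ids, c("s1", "s2", "s3"))
  expect_equal(inputs$dropped_samples, "sm_only")
  expect_equal(nrow(inputs$samples), 3L)
})

test_that("read_assays derives betas from intensity pairs", {
  dir <- withr::local_tempdir()
  M <- matrix(c(100, 900, 0, 300), 2, dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  U <- matrix(c(0, 0, 500, 100), 2, dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  write_matrix_file(M, file.path(dir, "M.tsv"), id_col = "probe_id")
  write_matrix_file(U, file.path(dir, "U.tsv"), id_col = "probe_id")
  expr <- matrix(rnorm(4, 8), 2, dimnames = list(c("GENEA", "GENEB"), c("s1", "s2")))
  write_matrix_file(expr, file.path(dir, "expr.tsv"), id_col = "gene_id")
  writeLines(c("probe_id\tchrom\tpos\tgene_symbols\tregion_labels",
               "cg1\tchr1\t100\tGENEA\tTSS200",
               "cg2\tchr1\t200\tGENEB\tBody"),
             file.path(dir, "annot.tsv"))
  writeLines(c("sample_id\tgroup", "s1\tcase", "s2\tcontrol"), file.path(dir, "samples.tsv"))
  inputs <- read_assays(NULL, file.path(dir, "annot.tsv"), file.path(dir, "expr.tsv"),
                        file.path(dir, "samples.tsv"),
                        meth_intensity_path = file.path(dir, "M.tsv"),
                        unmeth_intensity_path = file.path(dir, "U.tsv"))
  expect_equal(inputs$methylation$source, "from_intensities")
  expect_equal(unname(inputs$methylation$beta["cg1", "s1"]), 0.5)
  expect_equal(unname(inputs$methylation$beta["cg2", "s2"]), 300 / 500)
})

test_that("DMS BED export is 0-based half-open", {
  site <- data.frame(feature = c("cg1", "cg2", "cg3"),
                     call = c("hyper", "none", "hypo"),
                     stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dms.bed")
  write_dms_bed(site, tiny_annotation(), p)
  bed <- read.table(p, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$V2, bed$V3 - 1L)
  expect_setequal(bed$V4, c("cg1", "cg3"))
})
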