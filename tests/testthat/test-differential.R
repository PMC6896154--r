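test_that("moderated test with d0 = 0 equals the textbook pooled t", {
  set.seed(101)
  n1 <- 7; n2 <- 5
  x <- matrix(rnorm(1000 * (n1 + n2)), 1000)
  groups <- rep(c("case", "control"), c(n1, n2))
  res <- moderated_two_sample_test(x, groups, d0 = 0)
  # independent oracle: the pooled-variance Student t, feature by feature
  oracle_t <- apply(x, 1, function(v) {
    a <- v[1:n1]; b <- v[(n1 + 1):(n1 + n2)]
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  })
  expect_equal(res$t, oracle_t, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(oracle_t), df = n1 + n2 - 2), tolerance = 1e-10)
})

test_that("moderated test matches limma's eBayes on random data", {
  skip_if_not_installed("limma")
  set.seed(102)
  n1 <- 6; n2 <- 8
  # heterogeneous variances so moderation actually does something
  x <- matrix(rnorm(300 * (n1 + n2), sd = rep(sqrt(rchisq(300, 4) / 4), n1 + n2)), 300)
  groups <- rep(c("case", "control"), c(n1, n2))
  res <- moderated_two_sample_test(x, groups)

  design <- cbind(1, as.integer(groups == "case"))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, fit$t[, 2], ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(res$p, fit$p.value[, 2], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("degenerate and untestable features are handled explicitly", {
  x <- rbind(c(1, 1, 1, 1), c(2, 2, 1, 1), c(1, NA, 2, 3))
  rownames(x) <- c("flat", "clean", "na_case")
  groups <- c("case", "case", "control", "control")
  expect_warning(res <- moderated_two_sample_test(x, groups), "fewer than 10")
  expect_equal(res$t[1], 0)        # identical group means, zero variance
  expect_equal(res$p[1], 1)
  expect_true(is.na(res$t[3]))     # < 2 non-missing case values: untestable
  expect_true(is.na(res$p[3]))
  expect_false(is.na(res$t[2]))
})

test_that("moderated t interpolates between ordinary t and the fixed-s0 z limit", {
  set.seed(103)
  x <- matrix(rnorm(200 * 10), 200)
  groups <- rep(c("case", "control"), each = 5)
  t0 <- moderated_two_sample_test(x, groups, d0 = 0)$t
  t_inf <- moderated_two_sample_test(x, groups, d0 = Inf)$t
  t_big <- moderated_two_sample_test(x, groups, d0 = 1e8)$t
  expect_equal(t_big, t_inf, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(t0, t_inf, tolerance = 1e-3)))
  # moderated |t| lies between the two extremes' shrinkage behaviour:
  # posterior variance is a convex combination of s_g^2 and s0^2
  res <- moderated_two_sample_test(x, groups)
  d0 <- attr(res, "d0"); s0 <- attr(res, "s0_sq")
  expect_true(d0 > 0)
  expect_true(s0 > 0)
})

test_that("bh_adjust equals the brute-force step-up on random vectors", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    raw <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(raw)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(104)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
    expect_identical(bh_adjust(p), p.adjust(p, "BH"))  # cross-check vs stats
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("bh_adjust passes NA through without counting it", {
  p <- c(0.01, NA, 0.02, 0.03, NA, 0.04)
  out <- bh_adjust(p)
  expect_true(all(is.na(out[c(2, 5)])))
  expect_identical(out[!is.na(p)], bh_adjust(p[!is.na(p)]))
})

test_that("DMS/DMR/DEG calls use strict thresholds", {
  tab <- data.frame(
    adj_p = c(0.01, 0.01, 0.06, 0.05, 0.01, NA),
    effect = c(0.25, 0.20, 0.50, 0.30, -0.21, 0.4)
  )
  expect_equal(call_dms(tab), c("hyper", "none", "none", "none", "hypo", "none"))
  expect_identical(call_dmr(tab), call_dms(tab))
  etab <- data.frame(
    adj_p = c(0.001, 0.001, 0.2, 0.001, 0.05),
    effect = c(3.1, -2.0, 5, -2.5, 4)
  )
  expect_equal(call_deg(etab), c("up", "none", "none", "down", "none"))
})

test_that("diff_methylation tests on M-values but filters on the beta scale", {
  set.seed(105)
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  samples <- tiny_samples(n, ids)
  # probe 1: large beta shift; probe 2: null; probes 3..30: null background
  beta0 <- runif(30, 0.3, 0.7)
  beta <- matrix(rep(beta0, n), 30, n, dimnames = list(sprintf("cg%02d", 1:30), ids))
  beta[1, samples$group == "case"] <- beta0[1] + 0.3
  beta <- beta + matrix(rnorm(30 * n, sd = 0.02), 30, n)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  assay <- methylation_assay(beta)
  res <- diff_methylation(assay, samples)
  expect_equal(res$call[1], "hyper")
  expect_true(all(res$call[-1] == "none"))
  # effect column is the arithmetic-mean beta difference, not an M difference
  b <- assay$beta
  expect_equal(res$effect,
               rowMeans(b[, samples$group == "case"]) - rowMeans(b[, samples$group == "control"]),
               ignore_attr = TRUE)
})

test_that("region-level BH families are adjusted separately per region label", {
  set.seed(106)
  cohort <- generate_cohort(small_sim_config(seed = 9))
  rm <- aggregate_regions(cohort$methylation, cohort$annotation)
  res <- diff_methylation(rm, cohort$samples)
  for (rg in unique(res$region)) {
    i <- res$region == rg
    expect_equal(res$adj_p[i], bh_adjust(res$p[i]))
  }
  # and the site level is a single family
  site <- diff_methylation(cohort$methylation, cohort$samples)
  expect_equal(site$adj_p, bh_adjust(site$p))
})

test_that("calls are invariant to sample permutation within groups", {
  cohort <- generate_cohort(small_sim_config(seed = 10))
  samples <- cohort$samples
  set.seed(107)
  perm <- c(sample(which(samples$group == "case")), sample(which(samples$group == "control")))
  samples_perm <- samples[perm, ]
  class(samples_perm) <- class(samples)
  r1 <- diff_methylation(cohort$methylation, samples)
  r2 <- diff_methylation(cohort$methylation, samples_perm)
  expect_equal(r1$t, r2$t)
  expect_identical(r1$call, r2$call)
})

test_that("derive_dmgs deduplicates genes and flags all-region calls", {
  region_tab <- data.frame(
    gene = c("A", "A", "A", "B", "C"),
    region = c("TSS1500", "TSS200", "Body", "TSS200", "Body"),
    call = c("hyper", "hyper", "hyper", "hypo", "none"),
    stringsAsFactors = FALSE
  )
  dmgs <- derive_dmgs(region_tab)
  expect_equal(nrow(dmgs), 2L)
  expect_true(dmgs$all_regions[dmgs$gene == "A"])
  expect_false(dmgs$all_regions[dmgs$gene == "B"])
  expect_equal(dmgs$n_regions_called[dmgs$gene == "A"], 3L)
  expect_equal(nrow(derive_dmgs(region_tab[region_tab$call == "none", ])), 0L)
})
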