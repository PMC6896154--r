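# Brute-force AUC oracle: correctly ordered case/control pairs + half ties.
pairwise_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]; ct <- scores[labels == "control"]
  pairs <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

test_that("trapezoid AUC equals the pairwise Mann-Whitney count exactly", {
  set.seed(301)
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    labels <- c(rep("case", n1), rep("control", n0))
    scores <- sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels)$auc, pairwise_auc(scores, labels))
  }
})

test_that("ROC curve starts at (0,0), ends at (1,1), is monotone", {
  set.seed(302)
  labels <- rep(c("case", "control"), each = 15)
  scores <- rnorm(30) + (labels == "case")
  roc <- roc_auc(scores, labels)$roc_points
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("AUC: perfect separation, symmetry, monotone-transform invariance", {
  labels <- rep(c("case", "control"), each = 10)
  scores <- c(rnorm(10, 5), rnorm(10, 0))
  expect_equal(roc_auc(scores, labels)$auc, 1)
  set.seed(303)
  s <- rnorm(20)
  expect_equal(roc_auc(s, labels)$auc + roc_auc(-s, labels)$auc, 1)
  expect_equal(roc_auc(exp(2 * s + 1), labels)$auc, roc_auc(s, labels)$auc)
  expect_error(roc_auc(s, rep("case", 20)), "both classes")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(304)
  labels <- rep(c("case", "control"), each = 25)
  aucs <- replicate(50, roc_auc(rnorm(50), sample(labels))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("auc_p_value: null center, perfect separation, permutation agreement", {
  labels <- rep(c("case", "control"), each = 20)
  # interleaved scores -> AUC exactly 0.5 -> p approximately 0.5
  scores <- rep(1:20, 2)
  expect_equal(roc_auc(scores, labels)$auc, 0.5)
  expect_equal(auc_p_value(scores, labels), 0.5, tolerance = 1e-6)
  # perfect separation at 20+20
  sep <- c(rnorm(20, 10), rnorm(20, 0))
  expect_lt(auc_p_value(sep, labels), 1e-6)
  # normal approximation tracks the permutation oracle at 8+8
  set.seed(305)
  lab8 <- rep(c("case", "control"), each = 8)
  s8 <- rnorm(16) + 0.8 * (lab8 == "case")
  p_norm <- auc_p_value(s8, lab8)
  p_perm <- auc_p_value(s8, lab8, method = "permutation", n_perm = 20000, seed = 1)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 20000)
  expect_lt(abs(p_norm - p_perm), 4 * mc_sd + 0.01)
})

test_that("pca_project: line data, orthonormal loadings, bounded variance", {
  set.seed(306)
  t_ <- rnorm(40)
  line2d <- cbind(2 * t_, -3 * t_) + matrix(rnorm(80, sd = 1e-6), 40)
  pc <- pca_project(line2d)
  expect_gt(pc$var_explained[1], 0.999)
  x <- matrix(rnorm(40 * 10), 40)
  pc <- pca_project(x, 4)
  expect_equal(crossprod(pc$loadings), diag(4), ignore_attr = TRUE, tolerance = 1e-8)
  expect_lte(sum(pc$var_explained), 1)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
})

test_that("loocv_scores honours its contract", {
  set.seed(307)
  labels <- rep(c("case", "control"), each = 10)
  x <- matrix(rnorm(20 * 5), 20)
  s <- loocv_scores(x, labels, classifier = "nearest_centroid")
  expect_length(s, 20)
  # constant features carry no signal: RF votes stay near chance
  xc <- matrix(1, 20, 5)
  s2 <- loocv_scores(xc, labels, n_trees = 101, seed = 5)
  expect_lt(abs(roc_auc(s2, labels)$auc - 0.5), 0.2)
  expect_error(loocv_scores(x, rep(c("case", "control"), c(1, 19))), ">= 2 samples")
  xna <- x; xna[1, 1] <- NA
  expect_error(loocv_scores(xna, labels), "NA")
})

test_that("LOOCV separates a planted signal and is deterministic given seed", {
  set.seed(308)
  labels <- rep(c("case", "control"), each = 20)
  x <- matrix(rnorm(40 * 50), 40)
  x[labels == "case", 1:10] <- x[labels == "case", 1:10] + 2
  s1 <- loocv_scores(x, labels, n_trees = 150, seed = 42)
  s2 <- loocv_scores(x, labels, n_trees = 150, seed = 42)
  expect_identical(s1, s2)
  expect_gte(roc_auc(s1, labels)$auc, 0.95)
  # nearest-centroid fallback also separates
  s3 <- loocv_scores(x, labels, classifier = "nearest_centroid")
  expect_gte(roc_auc(s3, labels)$auc, 0.95)
})

test_that("evaluate_feature_set assembles a coherent report", {
  set.seed(309)
  labels <- rep(c("case", "control"), each = 12)
  x <- matrix(rnorm(24 * 20), 24)
  x[labels == "case", 1:5] <- x[labels == "case", 1:5] + 3
  ev <- evaluate_feature_set(x, labels, "demo", n_trees = 150, seed = 3)
  expect_s3_class(ev, "evaluation_report")
  expect_length(ev$scores, 24)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_equal(ev$auc, roc_auc(ev$scores, labels)$auc)
  expect_equal(ev$n_case, 12)
})

test_that("stratified_evaluate dichotomizes age at 50 and skips thin strata", {
  set.seed(310)
  n <- 44
  labels <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 10), n)
  x[labels == "case", 1:4] <- x[labels == "case", 1:4] + 3
  age <- sample(c(35:50, 51:80), n, replace = TRUE)
  st <- stratified_evaluate(x, labels, age, "age", n_trees = 150, seed = 2)
  expect_setequal(names(st), c("<=50", ">50"))
  for (s in st) expect_gte(s$auc, 0.9)
  # stage grouping pools III and IV
  stage <- rep(c("I", "II", "III", "IV"), length.out = n)
  st2 <- stratified_evaluate(x, labels, stage, "stage", n_trees = 101, seed = 2)
  expect_true(all(names(st2) %in% c("I", "II", "III_IV")))
  # a stratum lacking one class is skipped with a warning
  cov2 <- ifelse(labels == "case", "A", "B")
  w <- capture_warnings(st3 <- stratified_evaluate(x, labels, cov2, "biased", n_trees = 51))
  expect_length(w, 2)       # one-class strata: both skipped
  expect_match(w, "skipped", all = TRUE)
  expect_length(st3, 0)
})

test_that("single-level covariate reproduces the global result", {
  set.seed(311)
  labels <- rep(c("case", "control"), each = 10)
  x <- matrix(rnorm(20 * 8), 20)
  st <- stratified_evaluate(x, labels, rep("all", 20), "dummy", n_trees = 101, seed = 9)
  glob <- loocv_scores(x, labels, n_trees = 101, seed = 9)
  expect_length(st, 1)
  expect_equal(st[[1]]$scores, glob)
  expect_equal(st[[1]]$auc, roc_auc(glob, labels)$auc)
})
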