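#' Random-forest case score
#'
#' Fits a bagged CART forest (gini splits, `mtry` features per split,
#' majority-vote leaves) on the training rows and returns, for each test
#' row, the fraction of trees voting "case" — the continuous score used for
#' ROC analysis. Each tree trains on a balanced bootstrap (min(n1, n0)
#' draws with replacement per class), so vote fractions are not biased by
#' class imbalance — leave-one-out folds always differ by one sample.
#' Deterministic given `seed`.
#'
#' @param x_train Sample-by-feature numeric training matrix.
#' @param y_train Labels ("case"/"control", factor or logical).
#' @param x_test Sample-by-feature test matrix.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param min_node Minimum node size to attempt a split (default 1).
#' @param seed Integer RNG seed for the forest.
#' @return Numeric vector of case-vote fractions, one per test row.
#' @export
rf_score <- function(x_train, y_train, x_test, n_trees = 500, mtry = NULL,
                     min_node = 1L, seed = 1L) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y <- as.integer(.as_case(y_train))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x_train))))
  .rf_vote(x_train, y, x_test, as.integer(n_trees), as.integer(mtry),
           as.integer(min_node), as.integer(seed))
}

#' Nearest-centroid case score
#'
#' Dependency-free fallback classifier: score = (distance to the control
#' centroid) minus (distance to the case centroid), so larger means more
#' case-like.
#'
#' @inheritParams rf_score
#' @return Numeric score per test row.
#' @export
nearest_centroid_score <- function(x_train, y_train, x_test) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y <- .as_case(y_train)
  mu_case <- colMeans(x_train[y, , drop = FALSE])
  mu_ctl <- colMeans(x_train[!y, , drop = FALSE])
  d_case <- sqrt(rowSums(sweep(x_test, 2L, mu_case)^2))
  d_ctl <- sqrt(rowSums(sweep(x_test, 2L, mu_ctl)^2))
  d_ctl - d_case
}

#' Leave-one-out cross-validated case scores
#'
#' For each sample i, a classifier is fitted on all samples except i and
#' used to score i, so no score comes from a model that saw its sample.
#'
#' @param features Sample-by-feature numeric matrix (no NA).
#' @param labels Per-sample labels ("case"/"control").
#' @param classifier `"random_forest"` (default) or `"nearest_centroid"`.
#' @param n_trees,mtry Forest hyperparameters (see [rf_score()]).
#' @param seed Integer seed; fold i uses seed + i so the whole procedure is
#'   deterministic given `seed`.
#' @return Numeric vector of length `nrow(features)`.
#' @export
loocv_scores <- function(features, labels,
                         classifier = c("random_forest", "nearest_centroid"),
                         n_trees = 500, mtry = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must not contain NA")
  y <- .as_case(labels)
  if (length(y) != nrow(features)) stop("labels must match feature rows")
  if (sum(y) < 2L || sum(!y) < 2L) {
    stop("each class needs >= 2 samples so every training fold contains both classes")
  }
  n <- nrow(features)
  vapply(seq_len(n), function(i) {
    tr <- features[-i, , drop = FALSE]
    te <- features[i, , drop = FALSE]
    if (classifier == "random_forest") {
      rf_score(tr, y[-i], te, n_trees = n_trees, mtry = mtry,
               seed = seed + i)
    } else {
      nearest_centroid_score(tr, y[-i], te)
    }
  }, numeric(1))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique score values (ties grouped into single
#' steps, i.e. the midrank convention); AUC by the trapezoid rule, which
#' then equals the Mann-Whitney pairwise statistic
#' (correctly ordered pairs + 0.5 * tied pairs) / (n1 * n0).
#'
#' @param scores Numeric case scores (larger = more case-like).
#' @param labels Per-sample labels ("case"/"control").
#' @return List: `roc_points` (data.frame `fpr`, `tpr`, starting at (0,0),
#'   ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_case(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- y[ord]
  block_end <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(l)[block_end] / n1)
  fpr <- c(0, cumsum(!l)[block_end] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' One-sided AUC significance
#'
#' p-value for H1: AUC > 0.5 from the Mann-Whitney U normal approximation
#' with tie correction (`method = "normal"`, default), or by Monte-Carlo
#' label permutation for small cohorts (`method = "permutation"`).
#'
#' @inheritParams roc_auc
#' @param method `"normal"` or `"permutation"`.
#' @param n_perm Number of label permutations (permutation method).
#' @param seed RNG seed for the permutation method.
#' @return p-value in (0, 1].
#' @export
auc_p_value <- function(scores, labels, method = c("normal", "permutation"),
                        n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  y <- .as_case(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  auc <- roc_auc(scores, labels)$auc
  if (method == "permutation") {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    hits <- vapply(seq_len(n_perm), function(i) {
      roc_auc(scores, sample(labels))$auc >= auc
    }, logical(1))
    return((sum(hits) + 1) / (n_perm + 1))
  }
  n <- n1 + n0
  u <- auc * n1 * n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n1 * n0 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(0.5)  # all scores tied: no information
  stats::pnorm((u - n1 * n0 / 2) / sqrt(sigma2), lower.tail = FALSE)
}

#' PCA projection of samples
#'
#' Column-centered (unscaled) SVD projection; components ordered by
#' decreasing variance explained.
#'
#' @param features Sample-by-feature matrix.
#' @param n_components Number of PCs to return (default 2).
#' @return List: `scores` (sample x PC), `var_explained` (fraction of total
#'   variance per returned PC), `loadings` (feature x PC, orthonormal).
#' @export
pca_project <- function(features, n_components = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("PCA needs >= 2 samples")
  n_components <- min(n_components, nrow(features) - 1L, ncol(features))
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  list(
    scores = pc$x[, keep, drop = FALSE],
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[keep],
    loadings = pc$rotation[, keep, drop = FALSE]
  )
}

#' Evaluate a feature set's case/control separability
#'
#' Runs LOOCV scoring, ROC/AUC with significance, and PCA for one feature
#' set, producing an evaluation report.
#'
#' @param features Sample-by-feature matrix.
#' @param labels Per-sample labels.
#' @param feature_set_name Name recorded in the report.
#' @inheritParams loocv_scores
#' @return An `evaluation_report`: list with `feature_set_name`, `scores`,
#'   `roc_points`, `auc`, `auc_p_value`, `pca`, `n_case`, `n_control`.
#' @export
evaluate_feature_set <- function(features, labels, feature_set_name = "features",
                                 classifier = c("random_forest", "nearest_centroid"),
                                 n_trees = 500, mtry = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  scores <- loocv_scores(features, labels, classifier, n_trees, mtry, seed)
  roc <- roc_auc(scores, labels)
  y <- .as_case(labels)
  structure(list(
    feature_set_name = feature_set_name,
    classifier = classifier,
    scores = scores,
    roc_points = roc$roc_points,
    auc = roc$auc,
    auc_p_value = auc_p_value(scores, labels),
    pca = pca_project(features),
    n_case = sum(y), n_control = sum(!y)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s, %s]: %d case / %d control, AUC = %.3f (p = %.3g)\n",
              x$feature_set_name, x$classifier, x$n_case, x$n_control,
              x$auc, x$auc_p_value))
  invisible(x)
}

#' Stratified separability analysis
#'
#' Re-runs LOOCV + ROC within each level of a clinical covariate, to check
#' that separability is not driven by that covariate. Age is dichotomized at
#' 50 years (`>50` vs `<=50`); stages III and IV are pooled. Strata with
#' fewer than 3 samples in either class are skipped with a warning.
#'
#' @param features Sample-by-feature matrix.
#' @param labels Per-sample labels.
#' @param covariate Per-sample covariate vector (numeric age, or categorical).
#' @param covariate_name Used for messages and level names.
#' @inheritParams loocv_scores
#' @return Named list of per-stratum reports: `auc`, `p`, `n`, `n_case`,
#'   `n_control`, `scores`; skipped strata are absent.
#' @export
stratified_evaluate <- function(features, labels, covariate,
                                covariate_name = "covariate",
                                classifier = c("random_forest", "nearest_centroid"),
                                n_trees = 500, mtry = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  features <- as.matrix(features)
  strata <- .stratify(covariate, covariate_name)
  y <- .as_case(labels)
  out <- list()
  for (lev in levels(strata)) {
    i <- which(!is.na(strata) & strata == lev)
    n_case <- sum(y[i]); n_ctl <- sum(!y[i])
    if (n_case < 3L || n_ctl < 3L) {
      warning(sprintf("stratum %s=%s skipped: %d case / %d control (< 3 per class)",
                      covariate_name, lev, n_case, n_ctl))
      next
    }
    sc <- loocv_scores(features[i, , drop = FALSE], labels[i],
                       classifier, n_trees, mtry, seed)
    out[[lev]] <- list(
      auc = roc_auc(sc, labels[i])$auc,
      p = auc_p_value(sc, labels[i]),
      n = length(i), n_case = n_case, n_control = n_ctl,
      scores = sc
    )
  }
  out
}

# Age -> >50 / <=50; stage -> I / II / III_IV; everything else by level.
.stratify <- function(covariate, name) {
  if (is.numeric(covariate)) {
    return(factor(ifelse(covariate > 50, ">50", "<=50"), levels = c("<=50", ">50")))
  }
  v <- as.character(covariate)
  if (name == "stage" || all(v %in% c("I", "II", "III", "IV", "III_IV", NA))) {
    v[v %in% c("III", "IV")] <- "III_IV"
    return(factor(v, levels = intersect(c("I", "II", "III_IV"), unique(v))))
  }
  factor(v)
}

.as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  v <- as.character(labels)
  bad <- setdiff(unique(v), c("case", "control"))
  if (length(bad) > 0L) stop("labels must be 'case'/'control'; found: ",
                             paste(bad, collapse = ", "))
  v == "case"
}
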