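#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-feature two-group comparison with variance moderation: the pooled
#' per-feature variance \eqn{s_g^2} (with \eqn{d_g = n_1 + n_2 - 2} df) is
#' shrunk towards a prior \eqn{(d_0, s_0^2)} estimated by moments matching on
#' \eqn{\log s_g^2} (digamma/trigamma inversion), giving
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' \deqn{t_g = (\bar{x}_{1g} - \bar{x}_{2g}) / (\tilde{s}_g \sqrt{1/n_1 + 1/n_2}),}
#' with two-sided p from a t reference on \eqn{d_0 + d_g} df (normal when
#' \eqn{d_0 = \infty}).
#'
#' NA cells are excluded pairwise. A feature with fewer than 2 non-missing
#' values in either group is marked untestable (NA statistics) rather than
#' dropped. Zero-variance features are excluded from the prior moment
#' matching; with fewer than 10 testable features the prior falls back to
#' \eqn{d_0 = 0} (ordinary pooled t) with a warning.
#'
#' @param values Feature-by-sample numeric matrix.
#' @param groups Factor/character per sample with exactly two levels;
#'   the contrast is `case - control` when levels are `control`, `case`,
#'   otherwise `level2 - level1`.
#' @param d0 Optional prior df override: `NULL` (estimate, default), `0`
#'   (ordinary pooled t) or `Inf` (z-like with fixed `s0`).
#' @return data.frame: `feature`, `mean_case`, `mean_control`, `effect`
#'   (difference of group means on the input scale), `t`, `p`, `df_total`,
#'   `n_case`, `n_control`; attributes `d0` and `s0_sq`.
#' @export
moderated_two_sample_test <- function(values, groups, d0 = NULL) {
  values <- as.matrix(values)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (length(groups) != ncol(values)) stop("groups length must match sample columns")
  lev <- levels(groups)
  if (setequal(lev, c("case", "control"))) lev <- c("control", "case")
  ctl <- values[, groups == lev[1L], drop = FALSE]
  cas <- values[, groups == lev[2L], drop = FALSE]

  n1 <- rowSums(!is.na(cas))
  n2 <- rowSums(!is.na(ctl))
  mean1 <- rowMeans(cas, na.rm = TRUE)
  mean2 <- rowMeans(ctl, na.rm = TRUE)
  v1 <- .row_var(cas, mean1, n1)
  v2 <- .row_var(ctl, mean2, n2)

  testable <- n1 >= 2L & n2 >= 2L
  dg <- ifelse(testable, n1 + n2 - 2, NA_real_)
  s2 <- ifelse(testable, ((n1 - 1) * v1 + (n2 - 1) * v2) / dg, NA_real_)

  prior <- .estimate_variance_prior(s2[testable], dg[testable], d0 = d0)
  d0 <- prior$d0; s0_sq <- prior$s0_sq

  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- dg
  } else {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- (mean1 - mean2) / se
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_stat)),
              2 * stats::pt(-abs(t_stat), df = df_total))
  # zero-variance features with zero effect: define t = 0, p = 1
  degenerate <- testable & !is.na(se) & se == 0
  t_stat[degenerate & (mean1 - mean2) == 0] <- 0
  p[degenerate & (mean1 - mean2) == 0] <- 1
  t_stat[!testable] <- NA_real_
  p[!testable] <- NA_real_

  out <- data.frame(
    feature = rownames(values) %||% as.character(seq_len(nrow(values))),
    mean_case = mean1, mean_control = mean2,
    effect = mean1 - mean2, t = t_stat, p = p, df_total = df_total,
    n_case = n1, n_control = n2,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

.row_var <- function(m, mu, n) {
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  ifelse(n >= 2L, ss / (n - 1), NA_real_)
}

# Moments-matching estimate of the scaled-F prior for residual variances:
# log s_g^2 has mean log s0^2 + psi(d_g/2) - log(d_g/2) - psi(d0/2) + log(d0/2)
# and excess variance psi'(d0/2) beyond psi'(d_g/2).
.estimate_variance_prior <- function(s2, dg, d0 = NULL, min_features = 10L) {
  keep <- !is.na(s2) & s2 > 0 & !is.na(dg) & dg > 0
  if (!is.null(d0)) {
    if (d0 == 0) return(list(d0 = 0, s0_sq = NA_real_))
  }
  if (sum(keep) < min_features) {
    if (is.null(d0)) {
      warning("fewer than 10 testable features; falling back to ordinary t (d0 = 0)")
      return(list(d0 = 0, s0_sq = NA_real_))
    }
  }
  z <- log(s2[keep])
  d <- dg[keep]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  if (!is.null(d0)) {
    if (is.infinite(d0)) return(list(d0 = Inf, s0_sq = exp(emean)))
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    return(list(d0 = d0, s0_sq = s0_sq))
  }
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d / 2))
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0_hat <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0_hat / 2) - log(d0_hat / 2))
  list(d0 = d0_hat, s0_sq = s0_sq)
}

#' Inverse of the trigamma function
#'
#' Newton iteration on `1/trigamma`, which is nearly linear; solves
#' `trigamma(y) = x` for `y > 0`.
#'
#' @param x Positive numeric vector.
#' @return y with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' \eqn{p_{(i)} \cdot m / i} with cumulative-min enforcement from the largest
#' p down, capped at 1. NA entries (untestable features) pass through and do
#' not count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  # ratio form: m/m == 1 exactly, so adjusted >= raw also in floating point
  adj <- pmin(1, cummin((m / (m:1)) * pv[o]))
  out[ok[o]] <- adj
  out
}

#' Call differentially methylated sites
#'
#' hyper if adj_p < 0.05 and delta beta > 0.2; hypo if adj_p < 0.05 and
#' delta beta < -0.2; otherwise none. All inequalities strict; boundary
#' values produce no call.
#'
#' @param tab data.frame with columns `adj_p` and `effect` (delta beta).
#' @param p_cut,effect_cut Thresholds (defaults 0.05 and 0.2).
#' @return Character vector in `{hyper, hypo, none}`.
#' @export
call_dms <- function(tab, p_cut = 0.05, effect_cut = 0.2) {
  .call_two_sided(tab$adj_p, tab$effect, p_cut, effect_cut, c("hyper", "hypo"))
}

#' Call differentially methylated regions
#'
#' Same rule as [call_dms()] applied to (gene, region) rows.
#'
#' @inheritParams call_dms
#' @return Character vector in `{hyper, hypo, none}`.
#' @export
call_dmr <- function(tab, p_cut = 0.05, effect_cut = 0.2) {
  call_dms(tab, p_cut, effect_cut)
}

#' Call differentially expressed genes
#'
#' up if adj_p < 0.05 and log2FC > 2; down if adj_p < 0.05 and
#' log2FC < -2; otherwise none (strict inequalities; logFC is a difference
#' of group means of log2 expression, so > 2 means > 4-fold).
#'
#' @param tab data.frame with columns `adj_p` and `effect` (log2FC).
#' @param p_cut,effect_cut Thresholds (defaults 0.05 and 2).
#' @return Character vector in `{up, down, none}`.
#' @export
call_deg <- function(tab, p_cut = 0.05, effect_cut = 2) {
  .call_two_sided(tab$adj_p, tab$effect, p_cut, effect_cut, c("up", "down"))
}

.call_two_sided <- function(adj_p, effect, p_cut, effect_cut, labels) {
  call <- rep("none", length(adj_p))
  sig <- !is.na(adj_p) & !is.na(effect) & adj_p < p_cut
  call[sig & effect > effect_cut] <- labels[1L]
  call[sig & effect < -effect_cut] <- labels[2L]
  call
}

#' Site- or region-level differential methylation
#'
#' Runs the moderated test on M-values, computes delta beta on the beta
#' scale, BH-adjusts p-values, and applies the DMS/DMR thresholds. The
#' test statistic lives on the M scale, the effect filter on the beta scale.
#'
#' BH families: all sites form one family; at region level each region label
#' is adjusted as its own family.
#'
#' @param x A [methylation_assay()] (site level) or the result of
#'   [aggregate_regions()] (region level).
#' @param samples A [sample_sheet()] aligned with the assay columns.
#' @param p_cut,effect_cut Call thresholds (defaults 0.05, 0.2).
#' @param d0 Optional prior-df override (see [moderated_two_sample_test()]).
#' @return data.frame: `feature` (probe id or "gene|region"), plus `gene`,
#'   `region`, `k` at region level; `effect` (delta beta), `t`, `p`,
#'   `adj_p`, `call`.
#' @export
diff_methylation <- function(x, samples, p_cut = 0.05, effect_cut = 0.2, d0 = NULL) {
  stopifnot(inherits(samples, "sample_sheet"))
  if (inherits(x, "methylation_assay")) {
    beta <- x$beta
    mvals <- beta_to_m(beta)
    res <- .meth_diff_core(mvals, beta, samples, d0)
    res$adj_p <- bh_adjust(res$p)
    res$call <- call_dms(res, p_cut, effect_cut)
    attr(res, "level") <- "site"
  } else if (inherits(x, "region_methylation")) {
    res <- .meth_diff_core(x$m_region, x$beta_region, samples, d0)
    res <- cbind(x$keys, res[, setdiff(names(res), "feature"), drop = FALSE])
    res$feature <- paste(res$gene, res$region, sep = "|")
    # each region label is its own BH family
    res$adj_p <- NA_real_
    for (rg in unique(res$region)) {
      i <- res$region == rg
      res$adj_p[i] <- bh_adjust(res$p[i])
    }
    res$call <- call_dmr(res, p_cut, effect_cut)
    attr(res, "level") <- "region"
  } else {
    stop("x must be a methylation_assay or region_methylation object")
  }
  res
}

.meth_diff_core <- function(mvals, beta, samples, d0) {
  ord <- match(samples$sample_id, colnames(mvals))
  if (anyNA(ord)) stop("sample sheet ids missing from assay columns")
  test <- moderated_two_sample_test(mvals[, ord, drop = FALSE], samples$group, d0 = d0)
  b <- beta[, ord, drop = FALSE]
  g <- samples$group
  b_case <- rowMeans(b[, g == "case", drop = FALSE], na.rm = TRUE)
  b_ctl <- rowMeans(b[, g == "control", drop = FALSE], na.rm = TRUE)
  data.frame(
    feature = test$feature,
    effect = delta_beta(b_case, b_ctl),
    beta_case = b_case, beta_control = b_ctl,
    t = test$t, p = test$p, df_total = test$df_total,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Differential expression
#'
#' Moderated test on log2 expression; effect = difference of group means of
#' log2 expression (log2 fold change); BH over all genes as one family.
#'
#' @param assay An [expression_assay()].
#' @param samples A [sample_sheet()].
#' @param p_cut,effect_cut Call thresholds (defaults 0.05, 2).
#' @param d0 Optional prior-df override.
#' @return data.frame: `feature` (gene), `effect` (log2FC), `t`, `p`,
#'   `adj_p`, `call` in `{up, down, none}`.
#' @export
diff_expression <- function(assay, samples, p_cut = 0.05, effect_cut = 2, d0 = NULL) {
  stopifnot(inherits(assay, "expression_assay"), inherits(samples, "sample_sheet"))
  ord <- match(samples$sample_id, assay$sample_ids)
  if (anyNA(ord)) stop("sample sheet ids missing from expression columns")
  test <- moderated_two_sample_test(assay$log2_expr[, ord, drop = FALSE],
                                    samples$group, d0 = d0)
  res <- data.frame(
    feature = test$feature, effect = test$effect,
    t = test$t, p = test$p, df_total = test$df_total,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$adj_p <- bh_adjust(res$p)
  res$call <- call_deg(res, p_cut, effect_cut)
  res
}

#' Differentially methylated genes from region calls
#'
#' A gene is a DMG if it has at least one called region. Returns one row per
#' DMG with its called regions, directions, and a flag marking genes called
#' in every analysed region.
#'
#' @param region_table Output of [diff_methylation()] at region level.
#' @param regions The analysed region set (for the all-region flag).
#' @return data.frame: `gene`, `n_regions_called`, `regions`, `directions`,
#'   `all_regions`.
#' @export
derive_dmgs <- function(region_table, regions = DEFAULT_REGIONS) {
  called <- region_table[region_table$call != "none", , drop = FALSE]
  if (nrow(called) == 0L) {
    return(data.frame(gene = character(0), n_regions_called = integer(0),
                      regions = character(0), directions = character(0),
                      all_regions = logical(0), stringsAsFactors = FALSE))
  }
  sp <- split(called, called$gene)
  out <- data.frame(
    gene = names(sp),
    n_regions_called = vapply(sp, nrow, integer(1)),
    regions = vapply(sp, function(d) paste(d$region, collapse = ";"), character(1)),
    directions = vapply(sp, function(d) paste(d$call, collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$all_regions <- vapply(sp, function(d) all(regions %in% d$region), logical(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
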