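#' Beta-value from methylated/unmethylated intensities
#'
#' Computes the methylation fraction estimate \eqn{\beta = M / (M + U + 100)}
#' from methylated (M) and unmethylated (U) probe intensities. The offset of
#' 100 stabilizes low-intensity probes and guarantees \eqn{\beta < 1}.
#' Vectorized elementwise; `M` and `U` may be matrices of equal dimension.
#'
#' @param meth Non-negative methylated-allele intensities.
#' @param unmeth Non-negative unmethylated-allele intensities, same shape.
#' @param offset Intensity offset added to the denominator (default 100).
#' @return Beta values in `[0, 1)`, same shape as the inputs.
#' @examples
#' compute_beta(100, 0)  # 0.5
#' compute_beta(900, 0)  # 0.9
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  if (length(meth) != length(unmeth)) {
    stop("`meth` and `unmeth` must have the same length/shape")
  }
  bad <- which(meth < 0 | unmeth < 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "negative intensities are not allowed (%d offending cells, first at index %d)",
      length(bad), bad[1L]
    ))
  }
  meth / (meth + unmeth + offset)
}

#' Beta/M-value conversions
#'
#' `beta_to_m()` is the logit2 transform \eqn{m = \log_2(\beta / (1 - \beta))},
#' the scale on which two-group tests are run (variance is more homogeneous
#' than on the beta scale). `m_to_beta()` is its inverse
#' \eqn{\beta = 2^m / (1 + 2^m)}.
#'
#' Values must lie strictly inside (0, 1); use [clamp_beta()] first for
#' file-supplied matrices that may contain exact 0/1.
#'
#' @param beta Beta values strictly in (0, 1). NA is passed through.
#' @param m M-values (any finite real). NA is passed through.
#' @return Numeric vector/matrix of the converted values.
#' @examples
#' beta_to_m(0.8)   # 2
#' m_to_beta(0)     # 0.5
#' @export
beta_to_m <- function(beta) {
  bad <- which(!is.na(beta) & (beta <= 0 | beta >= 1))
  if (length(bad) > 0L) {
    stop(sprintf(
      "beta values must lie strictly in (0,1); %d offending cells (first: %g). Clamp first with clamp_beta().",
      length(bad), beta[bad[1L]]
    ))
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # 2^m/(1+2^m), written to avoid overflow for large |m|
  ifelse(m > 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
}

#' Clamp beta values away from 0 and 1
#'
#' External beta matrices can contain exact 0/1 values, which map to infinite
#' M-values. Clamps into `[eps, 1 - eps]` and reports how many cells moved.
#'
#' @param beta Numeric vector/matrix of beta values in `[0, 1]`.
#' @param eps Clamping bound (default 1e-6).
#' @param quiet Suppress the clamping message.
#' @return Clamped values, with attribute `n_clamped`.
#' @export
clamp_beta <- function(beta, eps = 1e-6, quiet = FALSE) {
  n_clamped <- sum(!is.na(beta) & (beta < eps | beta > 1 - eps))
  out <- pmin(pmax(beta, eps), 1 - eps)
  if (!is.null(dim(beta))) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  if (n_clamped > 0 && !quiet) {
    message(sprintf("clamp_beta: %d cells clamped into [%g, %g]", n_clamped, eps, 1 - eps))
  }
  attr(out, "n_clamped") <- n_clamped
  out
}
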