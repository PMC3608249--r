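# Multiple-testing support: effective number of independent tests (Li-Ji
# eigenvalue estimator), per-test significance thresholds, and BH-FDR for
# expression detection.

#' Effective number of independent tests (Li-Ji estimator)
#'
#' From the eigenvalues lambda of the correlation matrix among test
#' variables: Meff = sum over i of 1(lambda_i >= 1) + (lambda_i -
#' floor(lambda_i)).  Equals M for independent variables and 1 under
#' perfect correlation.
#'
#' @param corr correlation matrix (symmetric, unit diagonal).
#' @param tol negative-eigenvalue tolerance before erroring.
#' @return Meff, a real number in [1, M].
#' @export
effective_tests <- function(corr, tol = 1e-6) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation matrix must have unit diagonal")
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -tol) {
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         format(min(lambda)), ")")
  }
  lambda <- pmax(lambda, 0)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' Per-test significance threshold for M tests
#'
#' Bonferroni gives alpha/M; Sidak gives 1 - (1 - alpha)^(1/M).
#'
#' @param alpha family-wise level in (0,1); the study convention uses 0.05
#'   (significant) and 0.10 (suggestive).
#' @param m_tests number of tests (>= 1), possibly the Li-Ji effective
#'   number.
#' @param method \code{"bonferroni"} (default) or \code{"sidak"}.
#' @return per-test p-value threshold.
#' @export
per_test_threshold <- function(alpha, m_tests,
                               method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (m_tests < 1) stop("m_tests must be >= 1")
  switch(method,
         bonferroni = alpha / m_tests,
         sidak = 1 - (1 - alpha)^(1 / m_tests))
}

#' Benjamini-Hochberg step-up selection
#'
#' @param p_values numeric p-values in [0,1].
#' @param q FDR level.
#' @return list with \code{adjusted} (BH-adjusted p-values, input order)
#'   and \code{selected} (logical, TRUE where adjusted <= q).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(list(adjusted = numeric(0), selected = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, selected = !is.na(adj) & adj <= q)
}
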