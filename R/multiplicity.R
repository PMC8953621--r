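# Multiple-comparison control: fixed Bonferroni for the regulator
# hypotheses and a PCA-based effective number of independent tests for the
# collinear NMR panel.

#' Effective number of independent tests from a PCA of the panel
#'
#' Eigendecomposes the correlation matrix of the (complete, imputed) panel
#' and returns the smallest number of principal components whose
#' cumulative variance share reaches `threshold` (default 99.5 percent).
#' Highly collinear panels need far fewer components than variables, so
#' the Bonferroni divisor shrinks accordingly. Using the correlation
#' matrix makes the count invariant to variable rescaling.
#'
#' @param panel numeric matrix or data.frame, subjects x variables, no
#'   missing values (impute and exclude first).
#' @param threshold cumulative variance fraction defining the count,
#'   default 0.995.
#' @param alpha_family family-wise error rate to divide, default 0.05.
#' @return object of class `effective_tests`: m_eff, eigenvalues
#'   (descending), threshold, alpha_family, alpha_corrected
#'   (= alpha_family / m_eff) and n_variables.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' panel <- cbind(x, x)  # duplicated variables: 3 effective tests
#' effective_tests(panel)$m_eff
#' @export
effective_tests <- function(panel, threshold = 0.995, alpha_family = 0.05) {
  X <- as.matrix(panel)
  if (!is.numeric(X)) stop("panel must be numeric")
  if (anyNA(X) || any(!is.finite(X)))
    stop("panel contains missing or non-finite values; impute first")
  if (nrow(X) < 3) stop("fewer than 3 subjects")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  m_eff <- which(cum >= threshold - 1e-12)[1]
  structure(
    list(m_eff = m_eff, eigenvalues = ev, threshold = threshold,
         alpha_family = alpha_family,
         alpha_corrected = alpha_family / m_eff,
         n_variables = ncol(X)),
    class = "effective_tests"
  )
}

#' @export
print.effective_tests <- function(x, ...) {
  cat(sprintf(
    "Effective tests: %d of %d variables (%.1f%% variance); alpha %g -> %.3g\n",
    x$m_eff, x$n_variables, 100 * x$threshold, x$alpha_family,
    x$alpha_corrected))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha_family family-wise error rate, default 0.05.
#' @param m number of (effective) tests, >= 1.
#' @return corrected per-test alpha, `alpha_family / m`. With the fixed
#'   family of 9 regulator hypotheses this gives 0.05/9 ~ 0.006; with 22
#'   effective NMR tests, 0.05/22 ~ 0.002.
#' @export
bonferroni_alpha <- function(alpha_family = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  if (alpha_family <= 0 || alpha_family >= 1)
    stop("alpha_family must be in (0, 1)")
  alpha_family / m
}

#' Bonferroni-corrected two-sided confidence level
#'
#' @param alpha_family family-wise error rate, default 0.05.
#' @param m number of (effective) tests, >= 1.
#' @return two-sided confidence level `1 - alpha_family / m`, suitable for
#'   the `conf_level` argument of [univariate_fit()].
#' @export
corrected_ci_level <- function(alpha_family = 0.05, m) {
  1 - bonferroni_alpha(alpha_family, m)
}
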