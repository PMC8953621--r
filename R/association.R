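# Univariate association screening: per-SD or per-unit linear effects,
# bootstrap R-squared distributions and the Spearman correlation matrix.

#' Univariate linear regression of outcome on one predictor
#'
#' Fits ordinary least squares of `y` on `x`, after standardizing `x` to
#' z-scores when `scaling = "per_sd"` (NMR panel convention) or leaving it
#' on its measurement scale when `scaling = "per_unit"` (regulator-protein
#' convention). Incomplete pairs are dropped.
#'
#' @param y outcome vector (LPL activity, uJ/s).
#' @param x predictor vector.
#' @param scaling `"per_sd"` or `"per_unit"`.
#' @param conf_level two-sided confidence level for the CI (pass a
#'   Bonferroni-widened level from [corrected_ci_level()] for corrected
#'   CIs).
#' @param predictor predictor name carried into the result.
#' @return one-row data.frame of class `association_result`: predictor,
#'   scaling, beta (uJ/s per SD or per unit), se, ci_low, ci_high, p_raw
#'   (two-sided t-test), r2_insample (percent), n_used.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.3 * scale(x) + rnorm(50, 0, 0.3)
#' univariate_fit(y, x, "per_sd")
#' @export
univariate_fit <- function(y, x, scaling = c("per_sd", "per_unit"),
                           conf_level = 0.95, predictor = "x") {
  scaling <- match.arg(scaling)
  ok <- !is.na(y) & !is.na(x)
  y <- as.numeric(y)[ok]
  x <- as.numeric(x)[ok]
  n <- length(y)
  if (n < 3) stop("fewer than 3 complete observations")
  if (length(unique(x)) < 2) stop("predictor is constant")
  xs <- if (scaling == "per_sd") as.numeric(standardize(x)) else x
  fit <- stats::lm(y ~ xs)
  beta <- unname(stats::coef(fit)[2])
  # classical OLS slope SE, R2 and two-sided t-test from the fit
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) / sum((xs - mean(xs))^2))
  tval <- beta / se
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  out <- data.frame(
    predictor = predictor, scaling = scaling, beta = beta, se = se,
    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
    p_raw = 2 * stats::pt(-abs(tval), df = n - 2),
    r2_insample = 100 * (1 - rss / tss),
    n_used = n, conf_level = conf_level, stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

#' Screen a panel of predictors against the outcome
#'
#' Runs [univariate_fit()] for every column of `panel` and stacks the
#' results.
#'
#' @param y outcome vector.
#' @param panel data.frame or matrix of predictors.
#' @param scaling `"per_sd"` or `"per_unit"` (applied to all predictors).
#' @param conf_level two-sided confidence level for all CIs.
#' @return data.frame with one `association_result` row per predictor.
#' @export
screen_panel <- function(y, panel, scaling = c("per_sd", "per_unit"),
                         conf_level = 0.95) {
  scaling <- match.arg(scaling)
  panel <- as.data.frame(panel)
  out <- do.call(rbind, lapply(names(panel), function(v) {
    univariate_fit(y, panel[[v]], scaling = scaling,
                   conf_level = conf_level, predictor = v)
  }))
  rownames(out) <- NULL
  out
}

#' Bootstrap distribution of the conditional R-squared
#'
#' Case resampling: (y, x) pairs are resampled jointly with replacement,
#' each draw keeping the original number of observations, and the
#' in-sample R-squared (percent) of the refitted univariate model is
#' recorded. Degenerate draws (constant resampled predictor) are redrawn
#' so that exactly `B` values are returned.
#'
#' @param y outcome vector.
#' @param x predictor vector.
#' @param B number of bootstrap resamples, default 10000.
#' @param seed integer seed or NULL for the current RNG state.
#' @param predictor predictor name carried into the result.
#' @return object of class `bootstrap_r2`: list with `predictor`,
#'   `draws` (length-B vector of R-squared percentages), `B`, `seed`,
#'   `n_used`, `n_degenerate` (redraw count) and `summary` (mean and
#'   percentiles).
#' @export
bootstrap_r2 <- function(y, x, B = 10000, seed = NULL, predictor = "x") {
  ok <- !is.na(y) & !is.na(x)
  y <- as.numeric(y)[ok]
  x <- as.numeric(x)[ok]
  n <- length(y)
  if (n < 3) stop("fewer than 3 complete observations")
  if (B < 1) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  draws <- numeric(B)
  n_degenerate <- 0L
  for (b in seq_len(B)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) > 0 && stats::var(y[i]) > 0) break
      n_degenerate <- n_degenerate + 1L
    }
    draws[b] <- 100 * stats::cor(x[i], y[i])^2
  }
  structure(
    list(predictor = predictor, draws = draws, B = B, seed = seed,
         n_used = n, n_degenerate = n_degenerate,
         summary = c(mean = mean(draws),
                     stats::quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975)))),
    class = "bootstrap_r2"
  )
}

#' @export
print.bootstrap_r2 <- function(x, ...) {
  cat(sprintf("Bootstrap R2 for '%s': B = %d, mean = %.2f%%, median = %.2f%%\n",
              x$predictor, x$B, x$summary[["mean"]], x$summary[["50%"]]))
  invisible(x)
}

#' Spearman rank-correlation matrix of a panel
#'
#' Pairwise-complete Spearman correlations (Pearson on average ranks, ties
#' averaged). Variable pairs with fewer than 3 complete observations are
#' flagged undefined (NA). For heatmap display the variables can be
#' ordered by average-linkage hierarchical clustering of the distance
#' 1 - |rho|.
#'
#' @param panel data.frame or matrix of numeric variables.
#' @param order `"hclust"` (default) or `"none"`.
#' @return object of class `spearman_matrix`: list with `rho` (symmetric,
#'   unit diagonal), `order` (display ordering of variable names) and
#'   `n_pairs` (pairwise complete counts).
#' @export
spearman_matrix <- function(panel, order = c("hclust", "none")) {
  order <- match.arg(order)
  X <- as.matrix(panel)
  if (!is.numeric(X)) stop("panel must be numeric")
  p <- ncol(X)
  rho <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  obs <- !is.na(X)
  n_pairs <- crossprod(obs)
  rho[n_pairs < 3] <- NA_real_
  diag(rho) <- 1
  ord <- colnames(X)
  if (order == "hclust" && p > 2 && !anyNA(rho)) {
    hc <- stats::hclust(stats::as.dist(1 - abs(rho)), method = "average")
    ord <- colnames(X)[hc$order]
  }
  structure(list(rho = rho, order = ord, n_pairs = n_pairs),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  p <- ncol(x$rho)
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("Spearman matrix: %d variables, |rho| median %.2f, max %.2f\n",
              p, stats::median(abs(off), na.rm = TRUE),
              max(abs(off), na.rm = TRUE)))
  invisible(x)
}
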