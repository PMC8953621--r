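# Pipeline orchestration and plot-ready artifact emission: cohort summary
# table, forest-plot table, bootstrap R2 violin table, ordered Spearman
# heatmap table, per-regulator scatter tables and a run manifest.

#' Run the full association pipeline
#'
#' Orchestrates the analysis end to end: obtain a cohort (synthetic via
#' [generate_cohort()] or a previously written one via [read_cohort()]),
#' impute left-censored panel cells, compute the cohort summary, screen
#' the NMR panel (per-SD effects) and the regulator proteins (per-unit
#' effects) with Bonferroni-corrected confidence intervals (PCA-based
#' effective test count for the collinear panel, fixed family size for the
#' regulators), bootstrap the conditional R-squared of every model, and
#' compute the ordered Spearman matrix. Missing-at-random subjects are
#' excluded per analysis.
#'
#' @param config a [cohort_config()] for synthetic input, or a character
#'   path stem for [read_cohort()].
#' @param out_dir output directory for artifacts; NULL to skip writing.
#' @param impute_q quantile for left-censored imputation, default 0.01.
#' @param variance_threshold cumulative variance fraction for the
#'   effective test count, default 0.995.
#' @param bootstrap_B bootstrap resamples per model, default 10000.
#' @param regulator_family number of regulator hypotheses for the fixed
#'   Bonferroni correction, default 9 (7 protein levels plus 2 ratios with
#'   ApoC2, the conventional regulator family).
#' @param alpha_family family-wise error rate, default 0.05.
#' @param seed integer seed driving generation and bootstraps.
#' @return invisibly, a list with the cohort, summary table, forest table,
#'   violin table, Spearman matrix, per-regulator scatter tables, the
#'   `effective_tests` object and the manifest; written as CSV/JSON when
#'   `out_dir` is given.
#' @examples
#' res <- run_pipeline(cohort_config(seed = 1), bootstrap_B = 50, seed = 1)
#' head(res$forest[order(-res$forest$r2_insample), ])
#' @export
run_pipeline <- function(config, out_dir = NULL, impute_q = 0.01,
                         variance_threshold = 0.995, bootstrap_B = 10000,
                         regulator_family = 9, alpha_family = 0.05,
                         seed = 1) {
  if (bootstrap_B < 1) stop("bootstrap_B must be at least 1")
  if (inherits(config, "cohort_config")) {
    if (is.null(config$seed)) config$seed <- seed
    gen <- generate_cohort(config)
    cohort <- gen$cohort
    truth <- gen$truth
  } else if (is.character(config)) {
    cohort <- read_cohort(config)
    truth <- NULL
  } else {
    stop("config must be a cohort_config or a path stem")
  }

  cohort <- impute_left_censored(cohort, q = impute_q)
  outcome_var <- attr(cohort, "outcome_var")
  nmr_vars <- attr(cohort, "nmr_vars")
  reg_vars <- attr(cohort, "regulator_vars")

  summary_tab <- summarize_cohort(cohort)

  # NMR panel: subjects complete for outcome + full panel, per-SD effects,
  # PCA-based effective test count on the analyzed panel.
  nmr_keep <- complete_for(cohort, c(outcome_var, nmr_vars))
  nmr_panel <- as.data.frame(cohort)[nmr_keep, nmr_vars, drop = FALSE]
  y_nmr <- cohort[[outcome_var]][nmr_keep]
  et <- effective_tests(nmr_panel, threshold = variance_threshold,
                        alpha_family = alpha_family)
  nmr_level <- corrected_ci_level(alpha_family, et$m_eff)
  forest_nmr <- screen_panel(y_nmr, nmr_panel, scaling = "per_sd",
                             conf_level = nmr_level)
  forest_nmr$alpha_corrected <- et$alpha_corrected
  forest_nmr$family <- "nmr"

  # Regulators: per-unit effects, fixed Bonferroni family, per-analysis
  # missing-at-random exclusion. The family comprises the protein levels
  # plus the ApoC1/ApoC2 and ApoC3/ApoC2 ratio hypotheses when the ApoC
  # proteins are present (9 hypotheses with the default panel).
  reg_pred <- stats::setNames(as.list(reg_vars), reg_vars)
  if (all(c("ApoC1", "ApoC2", "ApoC3") %in% reg_vars)) {
    reg_pred$ApoC1_ApoC2 <- c("ApoC1", "ApoC2")
    reg_pred$ApoC3_ApoC2 <- c("ApoC3", "ApoC2")
  }
  reg_level <- corrected_ci_level(alpha_family, regulator_family)
  forest_reg <- do.call(rbind, lapply(names(reg_pred), function(v) {
    vars <- reg_pred[[v]]
    keep <- complete_for(cohort, c(outcome_var, vars))
    x <- if (length(vars) == 2) {
      cohort[[vars[1]]][keep] / cohort[[vars[2]]][keep]
    } else {
      cohort[[vars]][keep]
    }
    univariate_fit(cohort[[outcome_var]][keep], x,
                   scaling = "per_unit", conf_level = reg_level,
                   predictor = v)
  }))
  forest_reg$alpha_corrected <- bonferroni_alpha(alpha_family,
                                                 regulator_family)
  forest_reg$family <- "regulator"

  forest <- rbind(forest_nmr, forest_reg)
  forest$significant <- forest$p_raw < forest$alpha_corrected
  rownames(forest) <- NULL

  # Bootstrap R2 distributions for every model.
  set.seed(seed + 1L)
  all_pred <- c(nmr_vars, reg_vars)
  violin <- do.call(rbind, lapply(all_pred, function(v) {
    keep <- complete_for(cohort, c(outcome_var, v))
    br <- bootstrap_r2(cohort[[outcome_var]][keep], cohort[[v]][keep],
                       B = bootstrap_B, predictor = v)
    data.frame(predictor = v, B = br$B, n_used = br$n_used,
               r2_mean = br$summary[["mean"]],
               r2_q025 = br$summary[["2.5%"]],
               r2_q25 = br$summary[["25%"]],
               r2_median = br$summary[["50%"]],
               r2_q75 = br$summary[["75%"]],
               r2_q975 = br$summary[["97.5%"]],
               stringsAsFactors = FALSE)
  }))

  rho <- spearman_matrix(nmr_panel, order = "hclust")

  scatter <- lapply(names(reg_pred), function(v) {
    vars <- reg_pred[[v]]
    keep <- complete_for(cohort, c(outcome_var, vars))
    x <- if (length(vars) == 2) {
      cohort[[vars[1]]][keep] / cohort[[vars[2]]][keep]
    } else {
      cohort[[vars]][keep]
    }
    y <- cohort[[outcome_var]][keep]
    fit <- stats::lm(y ~ x)
    pr <- stats::predict(fit, se.fit = TRUE)
    data.frame(predictor = v, x = x, y = y, fitted = pr$fit,
               se_fit = pr$se.fit, stringsAsFactors = FALSE)
  })
  names(scatter) <- names(reg_pred)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lipolyzer")),
    seed = seed, bootstrap_B = bootstrap_B, impute_q = impute_q,
    variance_threshold = variance_threshold,
    alpha_family = alpha_family,
    m_eff = et$m_eff,
    alpha_nmr = et$alpha_corrected,
    alpha_regulators = bonferroni_alpha(alpha_family, regulator_family),
    n_subjects = nrow(cohort),
    n_nmr_used = sum(nmr_keep),
    n_used_per_regulator = stats::setNames(
      forest_reg$n_used, forest_reg$predictor)
  )

  result <- list(cohort = cohort, truth = truth, summary = summary_tab,
                 forest = forest, violin = violin, spearman = rho,
                 scatter = scatter, effective_tests = et,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(forest, file.path(out_dir, "forest.csv"),
                     row.names = FALSE)
    utils::write.csv(violin, file.path(out_dir, "violin.csv"),
                     row.names = FALSE)
    rho_ord <- rho$rho[rho$order, rho$order]
    utils::write.csv(
      data.frame(variable = rownames(rho_ord), rho_ord, check.names = FALSE),
      file.path(out_dir, "heatmap.csv"), row.names = FALSE)
    for (v in names(scatter)) {
      utils::write.csv(scatter[[v]],
                       file.path(out_dir, paste0("scatter_", v, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
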