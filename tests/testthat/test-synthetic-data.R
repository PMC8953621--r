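# Generator: determinism, marginals, collinearity structure, censoring
# rules and thermogram construction.

test_that("generation is deterministic under a seed and varies across seeds", {
  g1 <- generate_cohort(small_config(seed = 5))
  g2 <- generate_cohort(small_config(seed = 5))
  g3 <- generate_cohort(small_config(seed = 6))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$latent_scores, g2$truth$latent_scores)
  expect_false(identical(g1$cohort$lpl_activity, g3$cohort$lpl_activity))
})

test_that("default outcome matches the configured mean and SD", {
  # n = 117 per cohort; averaging over 20 seeds shrinks the SE of the
  # mean to 0.37/sqrt(20*117) ~ 0.0077 and of the SD to ~0.006
  stats <- vapply(1:20, function(s) {
    y <- generate_cohort(cohort_config(seed = s))$cohort$lpl_activity
    c(mean(y), sd(y))
  }, numeric(2))
  expect_lt(abs(mean(stats[1, ]) - 0.72), 4 * 0.37 / sqrt(20 * 117))
  expect_lt(abs(mean(stats[2, ]) - 0.37), 0.025)
})

test_that("regulator marginals track their configured medians", {
  rm <- default_regulator_marginals()
  meds <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_config(seed = s, mar_counts = NULL))$cohort
    vapply(rm$protein, function(v) median(co[[v]]), numeric(1))
  }, numeric(nrow(rm)))
  rel_err <- abs(rowMeans(meds) - rm$median) / rm$median
  expect_true(all(rel_err < 0.10))
})

test_that("shared-factor blocks are strongly rank-correlated", {
  pairs <- list(c("XXL_VLDL_P", "XL_VLDL_TG"), c("VLDL_D", "Tot_TG"),
                c("XL_HDL_P", "HDL_D"))
  for (s in 1:25) {
    co <- generate_cohort(cohort_config(seed = s, censor_fraction = 0))$cohort
    for (p in pairs) {
      expect_gte(cor(co[[p[1]]], co[[p[2]]], method = "spearman"), 0.8)
    }
  }
})

test_that("a global-null cohort shows only null-band outcome correlations", {
  g <- generate_cohort(null_config(seed = 21))
  co <- impute_left_censored(g$cohort)
  y <- co$lpl_activity
  set.seed(99)
  for (v in c("VLDL_D", "HDL_D", "Tot_TG", "ApoC2", "FA_w6_ratio")) {
    obs <- abs(cor(y, co[[v]], method = "spearman", use = "complete.obs"))
    perm <- replicate(400, abs(cor(sample(y), co[[v]], method = "spearman",
                                   use = "complete.obs")))
    expect_lt(obs, quantile(perm, 0.999))
  }
})

test_that("left-censoring hits the configured count, subjects and tail", {
  set.seed(4)
  panel <- matrix(rnorm(117 * 94), 117, 94,
                  dimnames = list(NULL, paste0("v", 1:94)))
  cen <- inject_censoring(panel, censor_fraction = 0.004, censor_subjects = 6)
  expect_equal(sum(cen$mask), round(0.004 * 117 * 94))  # 44 cells
  expect_lte(length(unique(row(panel)[cen$mask])), 6)
  # every masked value lies at or below its variable's empirical 10th
  # percentile (computed on the pre-censoring panel)
  thr <- apply(panel, 2, quantile, probs = 0.1, type = 7)
  expect_true(all(cen$original$value <=
                    thr[cen$original$variable] + 1e-12))
  # originals retained, masked cells NA
  expect_true(all(is.na(cen$panel[cen$mask])))
  expect_equal(panel[!cen$mask], cen$panel[!cen$mask])

  none <- inject_censoring(panel, censor_fraction = 0)
  expect_false(any(none$mask))
  expect_identical(none$panel, panel)
  expect_error(inject_censoring(panel, censor_fraction = 1), "\\[0, 1\\)")
})

test_that("config validation enforces the documented invariants", {
  expect_error(cohort_config(n_subjects = 2), "at least 3")
  expect_error(cohort_config(censor_fraction = 1), "\\[0, 1\\)")
  expect_error(cohort_config(true_effects = c(nonexistent_var = 1)),
               "panel or regulator")
  L <- default_nmr_loadings(94)
  expect_error(cohort_config(n_nmr_vars = 50, latent_loadings = L),
               "one row per")
})

test_that("noiseless thermograms are flat outside peaks and shift linearly", {
  tg <- generate_thermogram(0, noise_sd = 0, peak_height = 5)
  pre <- tg$power[tg$time < 60]
  expect_equal(max(pre) - min(pre), 0)
  late <- tg$power[tg$time > 1100]  # well past the last peak
  expect_lt(max(late) - min(late), 1e-4)

  tg2 <- generate_thermogram(0.72, noise_sd = 0)
  a <- activity_from_thermogram(tg2)
  expect_equal(a$delta_p_raw, 0.72, tolerance = 1e-12)
  expect_equal(a$shifts[3], 0.72 * 2.9297450, tolerance = 1e-5)
})
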