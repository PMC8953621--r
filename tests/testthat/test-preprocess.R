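# Unit conversions, imputation, missing-data policy, standardization and
# cohort summaries.

test_that("mixing arithmetic reproduces the buffering protocol", {
  expect_equal(mix_concentration(200, 40, 360), 20)  # Tris into plasma
  expect_equal(mix_concentration(10, 5, 5), 5)
  expect_equal(mix_concentration(10, 5, 0), 10)
  expect_error(mix_concentration(-1, 1, 1), "non-negative")
  expect_error(mix_concentration(1, 0, 0), "zero")
})

test_that("mass-to-molar conversions reproduce the regulator levels", {
  mw <- molecular_weights()
  # ApoC1 median 57 ug/ml -> 6.1 uM
  apoc1 <- mass_to_molar(57, "ug/ml", mw[["ApoC1"]], "uM")
  expect_equal(apoc1, 6.10801, tolerance = 1e-5)
  expect_equal(round(apoc1, 1), 6.1)
  # ApoC3 median 14.0 mg/dl -> 12.9 uM
  apoc3 <- mass_to_molar(14.0, "mg/dl", mw[["ApoC3"]], "uM")
  expect_equal(apoc3, 12.90085, tolerance = 1e-5)
  expect_equal(round(apoc3, 1), 12.9)
  # ApoA5 median 10.8 ng/ml -> 0.26 nM, presents as 0.3 nM
  apoa5 <- mass_to_molar(10.8, "ng/ml", mw[["ApoA5"]], "nM")
  expect_equal(apoa5, 0.2621359, tolerance = 1e-6)
  expect_equal(round(apoa5, 1), 0.3)
  expect_error(mass_to_molar(1, "stones/pint", 100), "unknown")
  expect_error(mass_to_molar(1, "ng/ml", -5), "positive")
})

test_that("unit conversions round-trip to machine precision", {
  set.seed(8)
  units <- c("g/l", "mg/ml", "mg/dl", "ug/ml", "ng/ml", "pg/ml")
  molar <- c("M", "mM", "uM", "nM", "pM")
  for (i in 1:20) {
    u <- sample(units, 1); m <- sample(molar, 1)
    conc <- runif(1, 0.1, 500); mw <- runif(1, 5e3, 5e5)
    back <- molar_to_mass(mass_to_molar(conc, u, mw, m), m, mw, u)
    expect_equal(back, conc, tolerance = 1e-12)
  }
  # micro sign and capital L are accepted spellings
  expect_equal(mass_to_molar(1, "µg/ml", 1000, "uM"),
               mass_to_molar(1, "ug/mL", 1000, "uM"))
})

test_that("left-censored imputation fills masked cells with the low quantile", {
  g <- generate_cohort(cohort_config(seed = 12))
  co <- g$cohort
  mask <- attr(co, "censor_mask")
  expect_gt(sum(mask), 0)
  before <- as.data.frame(co)
  imp <- impute_left_censored(co, q = 0.01)
  for (v in colnames(mask)[colSums(mask) > 0]) {
    obs <- before[[v]][!mask[, v]]
    expected <- quantile(obs[!is.na(obs)], 0.01, type = 7, names = FALSE)
    expect_equal(unique(imp[[v]][mask[, v]]), expected)
    # observed cells untouched
    expect_equal(imp[[v]][!mask[, v]], before[[v]][!mask[, v]])
  }
  expect_false(anyNA(as.data.frame(imp)[, attr(imp, "nmr_vars")]))
  # type-7 quantile oracle: observed 1..100 at q = 0.01 gives 1.99
  expect_equal(quantile(1:100, 0.01, type = 7, names = FALSE), 1.99)
  # no censored cells: unchanged
  g0 <- generate_cohort(cohort_config(seed = 12, censor_fraction = 0))
  expect_identical(impute_left_censored(g0$cohort), g0$cohort)
})

test_that("imputation errors when a variable has no observed values", {
  g <- generate_cohort(small_config(seed = 3))
  co <- g$cohort
  mask <- attr(co, "censor_mask")
  mask[, "VLDL_D"] <- TRUE
  co$VLDL_D <- NA_real_
  attr(co, "censor_mask") <- mask
  expect_error(impute_left_censored(co), "no observed values")
})

test_that("missing-at-random exclusion is per analysis, censoring is not", {
  g <- generate_cohort(cohort_config(
    seed = 9, mar_counts = c(ApoC1 = 1, ANGPTL4 = 2)))
  co <- g$cohort
  counts <- n_obs(co, c("lpl_activity", "ApoC1", "ANGPTL4", "ApoC3"))
  expect_equal(unname(counts), c(117, 116, 115, 117))
  # the ApoC1 analysis loses exactly its own MAR subject
  expect_equal(sum(complete_for(co, c("lpl_activity", "ApoC1"))), 116)
  expect_equal(sum(complete_for(co, c("lpl_activity", "ApoC3"))), 117)
  ex <- exclude_missing_at_random(co, c("lpl_activity", "ApoC1", "ANGPTL4"))
  expect_equal(nrow(ex), 114)
  expect_equal(nrow(attr(ex, "censor_mask")), 114)
  # censored NMR cells do not exclude subjects: panel analyses keep all
  # subjects once imputed
  imp <- impute_left_censored(co)
  expect_equal(sum(complete_for(imp, attr(imp, "nmr_vars"))), 117)
})

test_that("standardization gives n-1 z-scores and is idempotent", {
  z <- standardize(c(-1, 1))
  expect_equal(as.numeric(z), c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_equal(attr(z, "scale"), sqrt(2))
  x <- rnorm(50, 5, 3)
  z1 <- standardize(x)
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_equal(sd(z1), 1, tolerance = 1e-12)
  z2 <- standardize(as.numeric(z1))
  expect_equal(as.numeric(z2), as.numeric(z1), tolerance = 1e-12)
  expect_error(standardize(rep(3, 10)), "distinct")
})

test_that("cohort summaries pick the branch the distribution calls for", {
  set.seed(15)
  d <- data.frame(
    sym = rnorm(300),              # |skewness| ~ 0: mean/SD branch
    skew = rlnorm(300, sdlog = 1), # log-normal: median/IQR branch
    sex = factor(sample(c("Male", "Female"), 300, replace = TRUE))
  )
  s <- summarize_cohort(d, vars = names(d))
  expect_equal(s$type[s$variable == "sym"], "mean_sd")
  expect_equal(s$type[s$variable == "skew"], "median_iqr")
  cat_rows <- s[s$type == "categorical", ]
  expect_equal(nrow(cat_rows), 2)
  expect_equal(sum(cat_rows$spread_low), 100)  # percentages sum to 100
  # n_obs reflects per-variable completeness
  d$sym[1:5] <- NA
  s2 <- summarize_cohort(d, vars = "sym")
  expect_equal(s2$n_obs, 295)
})
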