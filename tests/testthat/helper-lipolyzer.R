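# Shared fixtures: small, fast configurations used across test files.

# A reduced cohort for tests that only need structure, not power.
small_config <- function(seed = 1, ...) {
  cohort_config(n_subjects = 40, seed = seed, ...)
}

# Global-null study conditions: no true effects, outcome SD equal to the
# total observed SD.
null_config <- function(seed) {
  cohort_config(true_effects = numeric(0), noise_sd_outcome = 0.37,
                seed = seed)
}

# Closed-form OLS slope oracle, independent of lm().
ols_slope_oracle <- function(y, x) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force Spearman: average ranks, then the Pearson product-moment
# formula written out.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
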