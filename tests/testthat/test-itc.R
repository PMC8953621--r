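# Dosing arithmetic, baseline extraction, standards correction and the
# linearity control.

test_that("injection increments follow volume-displacement dilution", {
  s <- injection_schedule()
  # hand iteration of c_syr * v / (V_cell + cumulative injected volume):
  # 40*0.2/200.2, 200/205.2, 200/210.2, 200/215.2
  expect_equal(injection_increment(s, 1), 0.03996004, tolerance = 1e-7)
  expect_equal(injection_increment(s, 2), 0.97465887, tolerance = 1e-7)
  expect_equal(injection_increment(s, 3), 0.95147479, tolerance = 1e-7)
  expect_equal(injection_increment(s, 4), 0.92936803, tolerance = 1e-7)
  # each substantive injection raises the cell concentration by ~1 nM
  expect_equal(round(injection_increment(s, 2)), 1)
  # cumulative concentration over the three 5 uL injections, and its ratio
  # to the first increment (the linear-response factor)
  cc <- cumulative_concentration(s)
  expect_equal(cc[4] - cc[1], 2.8555017, tolerance = 1e-6)
  expect_equal((cc[4] - cc[1]) / (cc[2] - cc[1]), 2.9297450,
               tolerance = 1e-6)
  expect_error(injection_increment(s, 5), "out of range")
})

test_that("noiseless thermograms yield exact baseline differences", {
  tg <- generate_thermogram(0.72, noise_sd = 0)
  bl <- fit_baselines(tg)
  # purge level is the zero point; first substantive injection sits
  # exactly true_shift below it
  purge_level <- bl$levels[1]
  expect_equal(purge_level - bl$levels[2], 0.72, tolerance = 1e-12)
  a <- activity_from_thermogram(tg)
  expect_equal(a$delta_p_raw, 0.72, tolerance = 1e-12)
  expect_equal(a$linearity_r2, 1, tolerance = 1e-9)
  expect_true(a$linear_ok)
  # linear response: shift after the third injection is 2.93x the first
  expect_equal(a$shifts[3] / a$shifts[1], 2.9297450, tolerance = 1e-6)

  flat <- generate_thermogram(0, noise_sd = 0)
  blf <- fit_baselines(flat)
  expect_equal(blf$baseline_pre, blf$levels[1], tolerance = 1e-12)
})

test_that("median baselines reach the expected Monte-Carlo accuracy", {
  # noise_sd 0.01 on >= 100-point windows: the median's error is within
  # 3 * 1.2533 * sd/sqrt(n_window) for ~99.7% of draws, and unbiased
  truth <- 0.5
  errs <- vapply(seq_len(200), function(s) {
    tg <- generate_thermogram(truth, noise_sd = 0.01, seed = s)
    activity_from_thermogram(tg)$delta_p_raw - truth
  }, numeric(1))
  n_win <- 140  # shortest analysis window (after the 100 s purge)
  per_baseline_se <- 1.2533 * 0.01 / sqrt(n_win)
  per_diff_se <- sqrt(2) * per_baseline_se
  expect_lt(mean(abs(errs) > 3 * per_diff_se), 0.02)
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("activity extraction is scale-equivariant", {
  tg <- generate_thermogram(0.4, noise_sd = 0.01, seed = 11)
  a1 <- activity_from_thermogram(tg)
  tg2 <- thermogram(tg$time, tg$power * 3, tg$schedule)
  a2 <- activity_from_thermogram(tg2)
  expect_equal(a2$delta_p_raw, 3 * a1$delta_p_raw, tolerance = 1e-10)
})

test_that("standards correction rescales by the bracketing mean", {
  expect_equal(standards_correction(0.5, standards_record(1, 1, 1)), 0.5)
  expect_equal(standards_correction(0.5, standards_record(1, 1.1, 1.1)),
               0.5 / 1.1)
  # before 10% low, after 10% high: arithmetic mean cancels the drift
  expect_equal(standards_correction(0.5, standards_record(1, 0.9, 1.1)), 0.5)
  # idempotent at the reference
  r <- standards_correction(0.7, standards_record(2, 2, 2))
  expect_equal(standards_correction(r, standards_record(2, 2, 2)), r)
  expect_error(standards_record(1, 0, 1), "positive")
})

test_that("linearity control passes proportional and flags saturating runs", {
  lin <- linearity_check(c(1, 2, 3) * 0.4, c(1, 2, 3))
  expect_equal(lin$r2, 1, tolerance = 1e-12)
  expect_true(lin$pass)
  # saturating response: r2 equals the squared correlation oracle, < 0.95
  shifts <- c(1, 1.5, 1.6)
  conc <- c(1, 2, 3)
  sat <- linearity_check(shifts, conc)
  expect_equal(sat$r2, cor(shifts, conc)^2, tolerance = 1e-12)
  expect_false(sat$pass)
  expect_error(linearity_check(1, 1), "at least 2")
  # unreliable extraction warns but still returns a result
  sched <- injection_schedule()
  tg <- generate_thermogram(0, noise_sd = 0.01, seed = 3, schedule = sched)
  expect_warning(a <- activity_from_thermogram(tg), "unreliable")
  expect_lt(a$delta_p_raw, 0.01)
})

test_that("thermogram validation rejects malformed input", {
  s <- injection_schedule()
  expect_error(thermogram(c(1, 2), c(1, 2, 3), s), "equal length")
  expect_error(thermogram(c(2, 1), c(1, 2), s), "increasing")
  expect_error(generate_thermogram(0.5, noise_sd = -1), "non-negative")
  short <- thermogram(seq(55, 500), rep(1, 446), s)
  expect_error(fit_baselines(short), "insufficient pre-injection")
})
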