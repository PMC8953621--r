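# Synthetic cohorts and thermograms with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: an NMR lipid panel driven by two latent particle-size factors
# (VLDL-size and HDL-size) producing block collinearity, skewed log-normal
# regulator-protein marginals parameterized by published medians/IQRs, an
# outcome (LPL activity, uJ/s) linear in chosen predictors, left-censored
# low-tail panel cells concentrated in a few subjects, and thermograms
# whose post-injection baseline shifts scale with cumulative enzyme
# concentration.

#' Default log-normal marginals for the LPL-regulator proteins
#'
#' Median and quartiles (units as measured by the respective immunoassays)
#' for the seven circulating LPL regulators, used to parameterize
#' log-normal generator marginals: meanlog = log(median),
#' sdlog = log(q75/q25) / (2 * qnorm(0.75)).
#'
#' @return data.frame with columns protein, unit, median, q25, q75.
#' @export
default_regulator_marginals <- function() {
  data.frame(
    protein = c("ANGPTL3", "ANGPTL4", "ANGPTL8",
                "ApoC1", "ApoC2", "ApoC3", "ApoA5"),
    unit = c("ng/ml", "ng/ml", "pg/ml", "ug/ml", "mg/dl", "mg/dl", "ng/ml"),
    median = c(236, 159, 1397, 57, 12.0, 14.0, 10.8),
    q25 = c(194, 97, 1051, 50, 8.4, 12.6, 5.9),
    q75 = c(301, 493, 1734, 66, 21.1, 17.5, 19.2),
    stringsAsFactors = FALSE
  )
}

#' Default latent-factor loading table for the synthetic NMR panel
#'
#' Builds a 2-factor loading scheme over `n_vars` lipoprotein/lipid
#' variables named in Nightingale style: a VLDL block (subclass particle
#' concentrations, triglyceride and cholesterol contents, mean diameter,
#' total triglycerides) loading highly on the VLDL-size factor; an HDL
#' block loading highly on the HDL-size factor (the smallest HDL subclass
#' loads negatively, as it moves opposite to the rest of the class); an
#' IDL/LDL block with moderate VLDL-factor loadings; and a fatty-acid /
#' composition block with mixed signed loadings (saturation measures
#' positive, omega-6/PUFA ratios negative on the VLDL-size factor). Each
#' variable keeps uniqueness `sqrt(1 - l1^2 - l2^2)` so its latent-scale
#' variance is 1 before the affine transform to concentration scale.
#'
#' @param n_vars number of panel variables (default 94). The named design
#'   covers 94 variables; other sizes recycle or truncate the scheme.
#' @return data.frame with columns variable, f_vldl, f_hdl, center, scale.
#' @export
default_nmr_loadings <- function(n_vars = 94) {
  blocks <- list()
  vldl_sub <- c("XXL_VLDL", "XL_VLDL", "L_VLDL", "M_VLDL", "S_VLDL", "XS_VLDL")
  for (s in vldl_sub) {
    for (comp in c("P", "TG", "C", "PL")) {
      blocks[[length(blocks) + 1]] <- data.frame(
        variable = paste0(s, "_", comp), f_vldl = 0.95, f_hdl = 0,
        center = 1.0, scale = 0.6)
    }
  }
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "VLDL_D", f_vldl = 0.95, f_hdl = 0, center = 36.9, scale = 1.3)
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "Tot_TG", f_vldl = 0.95, f_hdl = 0, center = 1.35, scale = 0.8)
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "TG_PG_ratio", f_vldl = 0.93, f_hdl = 0, center = 0.6,
    scale = 0.25)

  idl_ldl <- c("IDL", "L_LDL", "M_LDL", "S_LDL")
  for (s in idl_ldl) {
    for (comp in c("P", "TG", "C", "PL")) {
      l <- if (comp == "TG") 0.6 else 0.35
      blocks[[length(blocks) + 1]] <- data.frame(
        variable = paste0(s, "_", comp), f_vldl = l, f_hdl = 0,
        center = 1.2, scale = 0.4)
    }
  }
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "LDL_D", f_vldl = -0.4, f_hdl = 0.3, center = 23.6,
    scale = 0.25)

  hdl_sub <- c("XL_HDL", "L_HDL", "M_HDL")
  for (s in hdl_sub) {
    for (comp in c("P", "TG", "C", "PL")) {
      blocks[[length(blocks) + 1]] <- data.frame(
        variable = paste0(s, "_", comp), f_vldl = 0, f_hdl = 0.95,
        center = 1.5, scale = 0.5)
    }
  }
  for (comp in c("P", "TG", "C", "PL")) {
    blocks[[length(blocks) + 1]] <- data.frame(
      variable = paste0("S_HDL_", comp), f_vldl = 0, f_hdl = -0.5,
      center = 1.8, scale = 0.3)
  }
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "HDL_D", f_vldl = 0, f_hdl = 0.95, center = 9.7, scale = 0.25)
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "HDL_C", f_vldl = 0, f_hdl = 0.9, center = 1.6, scale = 0.45)
  blocks[[length(blocks) + 1]] <- data.frame(
    variable = "ApoA1", f_vldl = 0, f_hdl = 0.85, center = 1.6, scale = 0.3)

  fa <- data.frame(
    variable = c("Tot_FA", "SFA", "MUFA", "PUFA", "FA_w6", "FA_w3", "LA",
                 "DHA", "SFA_ratio", "MUFA_ratio", "PUFA_ratio",
                 "FA_w6_ratio", "FA_w3_ratio", "LA_ratio", "DHA_ratio",
                 "Unsat_deg"),
    f_vldl = c(0.7, 0.7, 0.75, 0.2, -0.1, 0.1, -0.1, 0.1,
               0.6, 0.65, -0.65, -0.7, -0.2, -0.6, -0.1, -0.7),
    f_hdl = c(0, 0, 0, 0.2, 0.25, 0.3, 0.25, 0.3,
              -0.2, -0.1, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    center = c(12, 4.3, 3.5, 4.5, 3.8, 0.6, 3.0, 0.2,
               36, 28, 37, 32, 4.5, 26, 1.5, 1.25),
    scale = c(2.5, 1.1, 1.0, 0.9, 0.8, 0.2, 0.7, 0.08,
              3, 3, 4, 3.5, 1.2, 3, 0.5, 0.1)
  )
  blocks[[length(blocks) + 1]] <- fa

  misc <- data.frame(
    variable = c("Tot_PG", "Tot_C", "Est_C", "Free_C", "SM",
                 "Phosphatidylc", "ApoB", "ApoB_ApoA1", "Remnant_C",
                 "VLDL_TG_total", "Serum_TG_HDL", "Clinical_LDL_C",
                 "Tot_L", "Glycerol", "Cholines"),
    f_vldl = c(0.3, 0.25, 0.2, 0.35, 0.2, 0.25, 0.45, 0.5, 0.5,
               0.9, 0.85, 0.2, 0.45, 0.4, 0.25),
    f_hdl = c(0.3, 0.2, 0.25, 0.1, 0.3, 0.3, -0.2, -0.5, -0.1,
              0, -0.3, 0, 0.3, 0, 0.35),
    center = c(2.8, 5.35, 3.7, 1.6, 0.5, 2.2, 1.0, 0.65, 0.55, 1.1, 0.9, 3.1,
               11, 0.15, 2.6),
    scale = c(0.4, 1.1, 0.8, 0.3, 0.1, 0.35, 0.25, 0.18, 0.2, 0.5, 0.45, 1.0,
              2.0, 0.05, 0.4)
  )
  blocks[[length(blocks) + 1]] <- misc

  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (n_vars <= nrow(out)) {
    out <- out[seq_len(n_vars), , drop = FALSE]
  } else {
    extra <- out[rep(seq_len(nrow(out)), length.out = n_vars - nrow(out)), ]
    extra$variable <- paste0(extra$variable, "_b")
    out <- rbind(out, extra)
    rownames(out) <- NULL
  }
  if (any(out$f_vldl^2 + out$f_hdl^2 > 1))
    stop("loadings imply negative uniqueness")
  out
}

#' Configuration for a synthetic cohort
#'
#' Defaults describe the study conditions the pipeline targets: 117
#' subjects, a 94-variable collinear NMR panel driven by VLDL-size and
#' HDL-size latent factors, outcome mean 0.72 uJ/s with total SD ~0.37
#' uJ/s, true per-SD effects of +0.2 uJ/s for the mean VLDL diameter and
#' -0.15 uJ/s for the mean HDL diameter, log-normal regulator marginals,
#' and 0.4 percent of panel cells left-censored across at most 6
#' subjects.
#'
#' @param n_subjects number of subjects, >= 3.
#' @param n_nmr_vars number of NMR panel variables.
#' @param latent_loadings loading table as from [default_nmr_loadings()].
#' @param true_effects named numeric vector: per-SD effect (uJ/s) of each
#'   named panel/regulator variable on the outcome; may be empty for a
#'   global null.
#' @param outcome_mean mean LPL activity, uJ/s.
#' @param noise_sd_outcome SD of the residual outcome noise, uJ/s. The
#'   default 0.273 combines with the default effects to a total outcome SD
#'   of ~0.37 uJ/s.
#' @param regulator_marginals data.frame as from
#'   [default_regulator_marginals()].
#' @param censor_fraction fraction of panel cells left-censored, in
#'   [0, 1).
#' @param censor_subjects maximum number of subjects carrying censored
#'   cells.
#' @param mar_counts named integer vector: number of subjects with a
#'   missing-at-random value per regulator (defaults mimic typical assay
#'   dropout: one subject each for ANGPTL4, ANGPTL8 and ApoC1).
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 117, n_nmr_vars = 94,
                          latent_loadings = default_nmr_loadings(n_nmr_vars),
                          true_effects = c(VLDL_D = 0.2, HDL_D = -0.15),
                          outcome_mean = 0.72, noise_sd_outcome = 0.273,
                          regulator_marginals = default_regulator_marginals(),
                          censor_fraction = 0.004, censor_subjects = 6,
                          mar_counts = c(ANGPTL4 = 1, ANGPTL8 = 1, ApoC1 = 1),
                          seed = NULL) {
  if (n_subjects < 3) stop("n_subjects must be at least 3")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must be in [0, 1)")
  if (nrow(latent_loadings) != n_nmr_vars)
    stop("latent_loadings must have one row per NMR variable")
  if (!all(is.finite(latent_loadings$f_vldl)) ||
      !all(is.finite(latent_loadings$f_hdl)))
    stop("loadings must be finite")
  if (noise_sd_outcome < 0) stop("noise_sd_outcome must be non-negative")
  known <- c(latent_loadings$variable, regulator_marginals$protein)
  if (length(true_effects) && !all(names(true_effects) %in% known))
    stop("true_effects names must be panel or regulator variables")
  structure(
    list(n_subjects = n_subjects, n_nmr_vars = n_nmr_vars,
         latent_loadings = latent_loadings, true_effects = true_effects,
         outcome_mean = outcome_mean, noise_sd_outcome = noise_sd_outcome,
         regulator_marginals = regulator_marginals,
         censor_fraction = censor_fraction,
         censor_subjects = censor_subjects, mar_counts = mar_counts,
         seed = seed),
    class = "cohort_config"
  )
}

#' Left-censor the low tail of a panel
#'
#' Selects cells for censoring only from the lowest-value tail of each
#' variable (below its empirical `tail_quantile` quantile), concentrated
#' in at most `censor_subjects` subjects (the subjects richest in
#' low-tail cells, as a shared limit of quantification affects whole
#' samples). Masked cells are set to `NA`; the original values are
#' returned for ground-truth bookkeeping.
#'
#' @param panel numeric matrix (subjects x variables).
#' @param censor_fraction fraction of all cells to censor, in [0, 1).
#' @param censor_subjects maximum number of affected subjects.
#' @param tail_quantile tail defining "censorable" values, default 0.1.
#' @return list with `panel` (masked cells NA), `mask` (logical matrix)
#'   and `original` (data.frame subject/variable/value of masked cells).
#' @export
inject_censoring <- function(panel, censor_fraction, censor_subjects = 6,
                             tail_quantile = 0.1) {
  stopifnot(is.matrix(panel), is.numeric(panel))
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must be in [0, 1)")
  mask <- matrix(FALSE, nrow(panel), ncol(panel),
                 dimnames = dimnames(panel))
  n_target <- round(censor_fraction * length(panel))
  if (n_target == 0)
    return(list(panel = panel, mask = mask,
                original = data.frame(subject = integer(), variable = character(),
                                      value = numeric())))
  thr <- apply(panel, 2, stats::quantile, probs = tail_quantile, type = 7)
  eligible <- sweep(panel, 2, thr, "<=")
  subj_order <- order(rowSums(eligible), decreasing = TRUE)
  chosen_subj <- subj_order[seq_len(min(censor_subjects, nrow(panel)))]
  pool <- which(eligible & (row(panel) %in% chosen_subj))
  if (length(pool) <= n_target) {
    cells <- pool
    if (length(pool) < n_target)
      warning("only ", length(pool), " low-tail cells available in ",
              censor_subjects, " subjects; censoring all of them")
  } else {
    cells <- sample(pool, n_target)
  }
  mask[cells] <- TRUE
  original <- data.frame(
    subject = row(panel)[cells],
    variable = colnames(panel)[col(panel)[cells]],
    value = panel[cells]
  )
  panel[cells] <- NA_real_
  list(panel = panel, mask = mask, original = original)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws latent VLDL-size and HDL-size factor scores per subject, builds
#' the NMR panel as loadings x factors plus idiosyncratic noise mapped to
#' concentration scale, draws regulator proteins from log-normal
#' marginals, forms the outcome as a linear combination of the
#' sample-standardized true-effect predictors plus Gaussian noise, applies
#' left-censoring to the panel's low tail and missing-at-random dropout to
#' the regulators.
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (an `lpl_cohort` data.frame carrying
#'   censoring/missingness masks and a unit registry as attributes) and
#'   `truth` (class `synthetic_truth`: true betas, latent scores, censor
#'   mask, pre-censoring values, per-subject true activity).
#' @examples
#' gc <- generate_cohort(cohort_config(n_subjects = 20, seed = 1))
#' dim(gc$cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  L <- config$latent_loadings
  p <- nrow(L)

  scores <- matrix(stats::rnorm(n * 2), n, 2,
                   dimnames = list(NULL, c("f_vldl", "f_hdl")))
  uniq <- sqrt(pmax(0, 1 - L$f_vldl^2 - L$f_hdl^2))
  latent <- scores %*% t(as.matrix(L[, c("f_vldl", "f_hdl")])) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(uniq, p)
  panel <- sweep(sweep(latent, 2, L$scale, "*"), 2, L$center, "+")
  colnames(panel) <- L$variable

  rm <- config$regulator_marginals
  regulators <- vapply(seq_len(nrow(rm)), function(i) {
    sdlog <- log(rm$q75[i] / rm$q25[i]) / (2 * stats::qnorm(0.75))
    stats::rlnorm(n, meanlog = log(rm$median[i]), sdlog = sdlog)
  }, numeric(n))
  colnames(regulators) <- rm$protein

  all_pred <- cbind(panel, regulators)
  eta <- rep(config$outcome_mean, n)
  if (length(config$true_effects)) {
    for (v in names(config$true_effects)) {
      z <- as.numeric(scale(all_pred[, v]))
      eta <- eta + config$true_effects[[v]] * z
    }
  }
  outcome <- eta + stats::rnorm(n, 0, config$noise_sd_outcome)

  cens <- inject_censoring(panel, config$censor_fraction,
                           config$censor_subjects)

  cohort <- data.frame(subject = seq_len(n), lpl_activity = outcome,
                       regulators, cens$panel, check.names = FALSE)
  mar_mask <- matrix(FALSE, n, nrow(rm), dimnames = list(NULL, rm$protein))
  if (length(config$mar_counts)) {
    for (v in names(config$mar_counts)) {
      k <- config$mar_counts[[v]]
      if (k > 0) {
        idx <- sample.int(n, k)
        cohort[[v]][idx] <- NA_real_
        mar_mask[idx, v] <- TRUE
      }
    }
  }

  units <- c(lpl_activity = "uJ/s",
             stats::setNames(rm$unit, rm$protein),
             stats::setNames(rep("panel unit", p), L$variable))
  attr(cohort, "censor_mask") <- cens$mask
  attr(cohort, "mar_mask") <- mar_mask
  attr(cohort, "units") <- units
  attr(cohort, "outcome_var") <- "lpl_activity"
  attr(cohort, "regulator_vars") <- rm$protein
  attr(cohort, "nmr_vars") <- L$variable
  class(cohort) <- c("lpl_cohort", "data.frame")

  truth <- structure(
    list(true_betas = config$true_effects, latent_scores = scores,
         censor_mask = cens$mask, censored_values = cens$original,
         thermogram_truth = outcome),
    class = "synthetic_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate an ITC thermogram with a known activity
#'
#' Produces a differential-power series with a flat pre-injection
#' baseline, a transient exponentially decaying artifact peak at each
#' injection, and post-injection baseline shifts proportional to the
#' cumulative injected enzyme concentration, normalized so the shift after
#' the first substantive injection equals `true_shift` (the purge
#' injection is the zero point). Lipolysis is exothermic: shifts are
#' applied downward; extraction reports magnitudes.
#'
#' @param true_shift baseline shift after the first substantive
#'   injection, uJ/s.
#' @param schedule an [injection_schedule()].
#' @param noise_sd SD of added Gaussian noise, uJ/s.
#' @param seed integer seed or NULL.
#' @param sampling_hz samples per second, default 1.
#' @param baseline pre-injection power level, uJ/s.
#' @param peak_height artifact peak amplitude, uJ/s.
#' @param peak_decay artifact exponential decay constant, s.
#' @param tail_s recording time after the last injection, s.
#' @param sample_id optional sample identifier.
#' @return a [thermogram()].
#' @export
generate_thermogram <- function(true_shift, schedule = injection_schedule(),
                                noise_sd = 0, seed = NULL, sampling_hz = 1,
                                baseline = 10, peak_height = 5,
                                peak_decay = 10, tail_s = NULL,
                                sample_id = NA_character_) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  inj <- schedule$injections
  if (nrow(inj) == 0) stop("schedule has no injections")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tail_s)) tail_s <- schedule$inter_injection_interval
  t_end <- max(inj$time) + tail_s
  time <- seq(0, t_end, by = 1 / sampling_hz)
  power <- rep(baseline, length(time))

  conc <- cumulative_concentration(schedule)
  purge_i <- which(inj$purge)[1]
  conc_zero <- if (!is.na(purge_i)) conc[purge_i] else 0
  first_sub <- which(!inj$purge)[1]
  if (is.na(first_sub)) stop("schedule has no substantive injection")
  denom <- conc[first_sub] - conc_zero

  conc_prev <- c(0, conc[-length(conc)])
  for (i in seq_len(nrow(inj))) {
    t0 <- inj$time[i]
    # artifact pulse with finite support (5 decay constants), so it dies
    # strictly inside the default peak-exclusion window
    pulse <- time >= t0 & time < t0 + 5 * peak_decay
    power[pulse] <- power[pulse] +
      peak_height * exp(-(time[pulse] - t0) / peak_decay)
    settled <- time >= t0 + inj$duration[i]
    # incremental downward shift; cumulatively the level after injection k
    # sits true_shift * (conc_k - conc_purge) / denom below the purge level
    power[settled] <- power[settled] -
      true_shift * (conc[i] - conc_prev[i]) / denom
  }
  if (noise_sd > 0)
    power <- power + stats::rnorm(length(power), 0, noise_sd)
  thermogram(time, power, schedule, sample_id = sample_id)
}
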