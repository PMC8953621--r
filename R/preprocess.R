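# Unit conversions, censored-value imputation, missing-data policy,
# standardization and cohort summaries.

# Mass-concentration units expressed in g/L; molar units in mol/L.
.mass_units <- c(
  "g/l" = 1, "mg/ml" = 1, "mg/dl" = 0.01, "ug/ml" = 1e-3,
  "ng/ml" = 1e-6, "pg/ml" = 1e-9
)
.molar_units <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "nM" = 1e-9, "pM" = 1e-12)

.normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit))
  sub("L", "l", u, fixed = TRUE)
}

.mass_unit_factor <- function(unit) {
  u <- tolower(.normalize_unit(unit))
  if (!u %in% names(.mass_units))
    stop("unknown mass-concentration unit: ", unit)
  .mass_units[[u]]
}

.molar_unit_factor <- function(unit) {
  u <- .normalize_unit(unit)
  if (!u %in% names(.molar_units))
    stop("unknown molar unit: ", unit)
  .molar_units[[u]]
}

#' Molar masses of the LPL-regulator proteins
#'
#' Named vector of molar masses (g/mol) used to convert the regulator
#' protein mass concentrations into molar concentrations. The
#' apolipoprotein entries are precursor (signal-peptide-included) masses,
#' which reproduce the conventional plasma conversions for ApoC1 and ApoC3;
#' ANGPTL entries are included for completeness.
#'
#' @param overrides optional named numeric vector replacing or extending
#'   the default entries.
#' @return named numeric vector of molar masses in g/mol.
#' @examples
#' molecular_weights()[["ApoC3"]]
#' @export
molecular_weights <- function(overrides = NULL) {
  mw <- c(
    ApoC1 = 9332, ApoC2 = 11284, ApoC3 = 10852, ApoA5 = 41200,
    ANGPTL3 = 53636, ANGPTL4 = 45214, ANGPTL8 = 22097
  )
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    mw[names(overrides)] <- overrides
  }
  if (any(mw <= 0)) stop("molar masses must be positive")
  mw
}

#' Final concentration after mixing two volumes
#'
#' Dilution arithmetic for sample preparation, e.g. buffering plasma:
#' mixing 40 uL of 200 mM Tris into 360 uL of plasma gives 20 mM Tris.
#'
#' @param stock_conc concentration of the stock solution (any unit).
#' @param stock_vol volume of stock added (same unit as `diluent_vol`).
#' @param diluent_vol volume of the diluent.
#' @return final concentration of the stock species, in the unit of
#'   `stock_conc`.
#' @examples
#' mix_concentration(200, 40, 360) # 20 mM Tris in buffered plasma
#' @export
mix_concentration <- function(stock_conc, stock_vol, diluent_vol) {
  if (any(c(stock_conc, stock_vol, diluent_vol) < 0))
    stop("concentrations and volumes must be non-negative")
  if (stock_vol + diluent_vol == 0)
    stop("total volume is zero")
  stock_conc * stock_vol / (stock_vol + diluent_vol)
}

#' Convert a mass concentration to a molar concentration
#'
#' @param conc numeric mass concentration value(s).
#' @param mass_unit unit of `conc`; one of g/l, mg/ml, mg/dl, ug/ml,
#'   ng/ml, pg/ml (mu accepted for u).
#' @param mw molar mass in g/mol.
#' @param molar_unit unit of the returned value; one of M, mM, uM, nM, pM.
#' @return molar concentration in `molar_unit`. No rounding is applied;
#'   round only at presentation.
#' @examples
#' mass_to_molar(14.0, "mg/dl", 10852, "uM")  # ApoC3 median, ~12.9 uM
#' mass_to_molar(57, "ug/ml", 9332, "uM")     # ApoC1 median, ~6.1 uM
#' @seealso [molar_to_mass()] for the inverse, [molecular_weights()].
#' @export
mass_to_molar <- function(conc, mass_unit, mw, molar_unit = "M") {
  if (!is.numeric(mw) || any(mw <= 0)) stop("mw must be positive")
  g_per_l <- conc * .mass_unit_factor(mass_unit)
  (g_per_l / mw) / .molar_unit_factor(molar_unit)
}

#' Convert a mass concentration between units
#'
#' @param conc numeric mass concentration value(s).
#' @param from,to units among g/l, mg/ml, mg/dl, ug/ml, ng/ml, pg/ml.
#' @return `conc` expressed in `to`.
#' @examples
#' convert_mass_conc(1397, "pg/ml", "ng/ml")  # ANGPTL8 median in ng/ml
#' @export
convert_mass_conc <- function(conc, from, to) {
  conc * .mass_unit_factor(from) / .mass_unit_factor(to)
}

#' Convert a molar concentration to a mass concentration
#'
#' @param conc numeric molar concentration value(s).
#' @param molar_unit unit of `conc` (M, mM, uM, nM, pM).
#' @param mw molar mass in g/mol.
#' @param mass_unit unit of the returned value (g/l, mg/ml, mg/dl, ug/ml,
#'   ng/ml, pg/ml).
#' @return mass concentration in `mass_unit`.
#' @export
molar_to_mass <- function(conc, molar_unit, mw, mass_unit = "g/l") {
  if (!is.numeric(mw) || any(mw <= 0)) stop("mw must be positive")
  mol_per_l <- conc * .molar_unit_factor(molar_unit)
  (mol_per_l * mw) / .mass_unit_factor(mass_unit)
}

#' Impute left-censored panel values by a deterministic low quantile
#'
#' Cells flagged as left-censored (below the limit of quantification) are
#' replaced by the q-quantile (type 7, linear interpolation) of the
#' observed values of their variable. The imputation is deterministic and
#' never alters observed cells. Missing-at-random cells are left missing.
#'
#' @param cohort an `lpl_cohort` object (see [generate_cohort()] or
#'   [read_cohort()]).
#' @param q quantile used as the imputed value, default 0.01.
#' @return the cohort with censored cells filled in; the censoring mask is
#'   retained (attribute `censor_mask`) but no censored-missing cells
#'   remain.
#' @export
impute_left_censored <- function(cohort, q = 0.01) {
  stopifnot(inherits(cohort, "lpl_cohort"), q >= 0, q < 1)
  mask <- attr(cohort, "censor_mask")
  if (is.null(mask) || !any(mask)) return(cohort)
  nmr_vars <- attr(cohort, "nmr_vars")
  for (v in colnames(mask)[colSums(mask) > 0]) {
    obs <- cohort[[v]][!mask[, v]]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0)
      stop("variable '", v, "' has no observed values to impute from")
    cohort[[v]][mask[, v]] <- stats::quantile(obs, q, type = 7, names = FALSE)
  }
  cohort
}

#' Subjects complete for a set of analysis variables
#'
#' Implements the missing-at-random policy: a subject is excluded from any
#' analysis whose variables contain a missing-at-random cell for that
#' subject. Left-censored cells never trigger exclusion (they are imputed
#' instead).
#'
#' @param cohort an `lpl_cohort`.
#' @param vars character vector of variable names used by the analysis.
#' @return logical vector over subjects, `TRUE` where the subject is
#'   usable for an analysis of `vars`.
#' @export
complete_for <- function(cohort, vars) {
  stopifnot(inherits(cohort, "lpl_cohort"), all(vars %in% names(cohort)))
  mar <- attr(cohort, "mar_mask")
  ok <- rep(TRUE, nrow(cohort))
  for (v in vars) {
    miss <- is.na(cohort[[v]])
    if (!is.null(mar) && v %in% colnames(mar)) miss <- miss & mar[, v]
    ok <- ok & !miss
  }
  ok
}

#' Listwise exclusion of subjects with missing-at-random values
#'
#' @param cohort an `lpl_cohort`.
#' @param vars variables whose completeness is required; default all
#'   analysis variables (outcome, regulators, NMR panel).
#' @return the cohort restricted to subjects with no missing-at-random
#'   cell in `vars`.
#' @export
exclude_missing_at_random <- function(cohort, vars = NULL) {
  stopifnot(inherits(cohort, "lpl_cohort"))
  if (is.null(vars))
    vars <- c(attr(cohort, "outcome_var"), attr(cohort, "regulator_vars"),
              attr(cohort, "nmr_vars"))
  keep <- complete_for(cohort, vars)
  subset_cohort(cohort, keep)
}

#' Per-variable number of complete observations
#'
#' @param cohort an `lpl_cohort`.
#' @param vars variables to count; default all analysis variables.
#' @return named integer vector of complete (non-missing-at-random,
#'   non-censored-missing) observation counts, as reported in cohort
#'   description tables.
#' @export
n_obs <- function(cohort, vars = NULL) {
  stopifnot(inherits(cohort, "lpl_cohort"))
  if (is.null(vars))
    vars <- c(attr(cohort, "outcome_var"), attr(cohort, "regulator_vars"),
              attr(cohort, "nmr_vars"))
  vapply(vars, function(v) sum(!is.na(cohort[[v]])), integer(1))
}

#' Standardize a numeric vector to z-scores
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), recording the original center and scale as attributes for
#' back-transformation of per-SD effect estimates.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector of z-scores with attributes `center` and
#'   `scale`. Standardizing an already-standardized vector is idempotent.
#' @export
standardize <- function(x) {
  x_obs <- x[!is.na(x)]
  if (length(unique(x_obs)) < 2) stop("x has fewer than 2 distinct values")
  s <- stats::sd(x_obs)
  if (s == 0) stop("x has zero variance")
  m <- mean(x_obs)
  z <- (x - m) / s
  attr(z, "center") <- m
  attr(z, "scale") <- s
  z
}

# Sample skewness (g1 = m3 / m2^(3/2)); used to pick the Table-1 summary
# branch.
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' Cohort description table
#'
#' Summarizes each variable the way clinical description tables do: mean
#' with SD and range for approximately symmetric variables, median with
#' IQR and range for skewed ones (|skewness| >= `skew_threshold`), and
#' counts with percentages for categorical variables. Counts of complete
#' observations (`n_obs`) are reported per variable.
#'
#' @param cohort an `lpl_cohort`, or a plain data.frame of variables.
#' @param vars variables to summarize; default outcome + regulators (the
#'   full NMR panel is summarized only on request).
#' @param skew_threshold absolute sample skewness above which the
#'   median/IQR branch is used, default 1.
#' @return data.frame with columns variable, unit, n_obs, type
#'   ("mean_sd", "median_iqr" or "categorical"), center, spread_low,
#'   spread_high, min, max, and a preformatted `label` column.
#' @export
summarize_cohort <- function(cohort, vars = NULL, skew_threshold = 1) {
  units <- attr(cohort, "units")
  if (is.null(vars)) {
    if (inherits(cohort, "lpl_cohort")) {
      vars <- c(attr(cohort, "outcome_var"), attr(cohort, "regulator_vars"))
    } else {
      vars <- names(cohort)
    }
  }
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    unit <- if (!is.null(units) && v %in% names(units)) units[[v]] else ""
    if (is.numeric(x)) {
      xo <- x[!is.na(x)]
      sk <- sample_skewness(xo)
      if (!is.na(sk) && abs(sk) >= skew_threshold) {
        qs <- stats::quantile(xo, c(0.25, 0.75), type = 7, names = FALSE)
        data.frame(
          variable = v, unit = unit, n_obs = length(xo), type = "median_iqr",
          center = stats::median(xo), spread_low = qs[1], spread_high = qs[2],
          min = min(xo), max = max(xo),
          label = sprintf("%.3g (IQR: %.3g-%.3g; range: %.3g-%.3g)",
                          stats::median(xo), qs[1], qs[2], min(xo), max(xo)),
          stringsAsFactors = FALSE
        )
      } else {
        data.frame(
          variable = v, unit = unit, n_obs = length(xo), type = "mean_sd",
          center = mean(xo), spread_low = mean(xo) - stats::sd(xo),
          spread_high = mean(xo) + stats::sd(xo),
          min = min(xo), max = max(xo),
          label = sprintf("%.3g (SD: +/-%.3g; range: %.3g-%.3g)",
                          mean(xo), stats::sd(xo), min(xo), max(xo)),
          stringsAsFactors = FALSE
        )
      }
    } else {
      xo <- x[!is.na(x)]
      tab <- table(xo)
      pct <- 100 * as.numeric(tab) / length(xo)
      data.frame(
        variable = paste0(v, ": ", names(tab)), unit = unit,
        n_obs = length(xo), type = "categorical",
        center = as.numeric(tab), spread_low = pct, spread_high = pct,
        min = NA_real_, max = NA_real_,
        label = sprintf("%d (%.1f%%)", as.numeric(tab), pct),
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Restrict a cohort to a logical/integer subject index, keeping masks and
# registries in step.
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "lpl_cohort"))
  at <- attributes(cohort)
  out <- as.data.frame(cohort)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (m in c("censor_mask", "mar_mask")) {
    if (!is.null(at[[m]])) at[[m]] <- at[[m]][idx, , drop = FALSE]
  }
  for (a in setdiff(names(at), c("names", "row.names", "class")))
    attr(out, a) <- at[[a]]
  class(out) <- c("lpl_cohort", "data.frame")
  out
}
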