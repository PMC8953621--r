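# Plain-text readers/writers for cohorts and thermograms.

#' Write a thermogram to CSV with a JSON schedule sidecar
#'
#' @param tg a [thermogram()].
#' @param csv_path output CSV path (columns time_s, power_uJ_per_s).
#' @param schedule_path output JSON path for the injection schedule;
#'   default replaces the CSV extension with `_schedule.json`.
#' @return invisibly, the two paths.
#' @export
write_thermogram <- function(tg, csv_path,
                             schedule_path = sub("\\.csv$",
                                                 "_schedule.json", csv_path)) {
  stopifnot(inherits(tg, "thermogram"))
  utils::write.csv(
    data.frame(time_s = tg$time, power_uJ_per_s = tg$power),
    csv_path, row.names = FALSE)
  sched <- tg$schedule
  jsonlite::write_json(
    list(syringe_conc = sched$syringe_conc, cell_volume = sched$cell_volume,
         inter_injection_interval = sched$inter_injection_interval,
         initial_delay = sched$initial_delay, injections = sched$injections,
         sample_id = tg$sample_id, temperature = tg$temperature),
    schedule_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, schedule = schedule_path))
}

#' Read a thermogram from CSV plus a JSON schedule sidecar
#'
#' @param csv_path CSV path with columns time_s, power_uJ_per_s.
#' @param schedule_path JSON path written by [write_thermogram()].
#' @return a [thermogram()].
#' @export
read_thermogram <- function(csv_path,
                            schedule_path = sub("\\.csv$",
                                                "_schedule.json", csv_path)) {
  d <- utils::read.csv(csv_path)
  if (!all(c("time_s", "power_uJ_per_s") %in% names(d)))
    stop("thermogram CSV needs columns time_s and power_uJ_per_s")
  s <- jsonlite::read_json(schedule_path, simplifyVector = TRUE)
  inj <- as.data.frame(s$injections)
  sched <- injection_schedule(
    syringe_conc = s$syringe_conc, cell_volume = s$cell_volume,
    n_substantive = sum(!inj$purge),
    substantive_volume = inj$volume[!inj$purge][1],
    purge_volume = if (any(inj$purge)) inj$volume[inj$purge][1] else 0,
    purge_duration = if (any(inj$purge)) inj$duration[inj$purge][1] else 100,
    injection_duration = inj$duration[!inj$purge][1],
    inter_injection_interval = s$inter_injection_interval,
    initial_delay = s$initial_delay)
  sched$injections <- inj  # preserve exact recorded times
  thermogram(d$time_s, d$power_uJ_per_s, sched,
             sample_id = if (is.null(s$sample_id)) NA_character_ else s$sample_id,
             temperature = if (is.null(s$temperature)) 25 else s$temperature)
}

#' Write a cohort to CSV with mask and unit sidecars
#'
#' Emits `<stem>.csv` (subjects x variables, censored/missing cells
#' empty), `<stem>_censor_mask.csv` and `<stem>_mar_mask.csv` ({0,1}
#' companions) and `<stem>_schema.json` (units and variable roles).
#'
#' @param cohort an `lpl_cohort`.
#' @param stem output path stem (no extension).
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "lpl_cohort"))
  paths <- c(data = paste0(stem, ".csv"),
             censor = paste0(stem, "_censor_mask.csv"),
             mar = paste0(stem, "_mar_mask.csv"),
             schema = paste0(stem, "_schema.json"))
  utils::write.csv(as.data.frame(cohort), paths["data"], row.names = FALSE)
  utils::write.csv(as.data.frame(attr(cohort, "censor_mask") * 1L),
                   paths["censor"], row.names = FALSE)
  utils::write.csv(as.data.frame(attr(cohort, "mar_mask") * 1L),
                   paths["mar"], row.names = FALSE)
  jsonlite::write_json(
    list(units = as.list(attr(cohort, "units")),
         outcome_var = attr(cohort, "outcome_var"),
         regulator_vars = attr(cohort, "regulator_vars"),
         nmr_vars = attr(cohort, "nmr_vars")),
    paths["schema"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param stem path stem used when writing.
#' @return an `lpl_cohort`.
#' @export
read_cohort <- function(stem) {
  d <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  cm <- as.matrix(utils::read.csv(paste0(stem, "_censor_mask.csv"),
                                  check.names = FALSE)) == 1
  mm <- as.matrix(utils::read.csv(paste0(stem, "_mar_mask.csv"),
                                  check.names = FALSE)) == 1
  schema <- jsonlite::read_json(paste0(stem, "_schema.json"),
                                simplifyVector = TRUE)
  attr(d, "censor_mask") <- cm
  attr(d, "mar_mask") <- mm
  attr(d, "units") <- unlist(schema$units)
  attr(d, "outcome_var") <- schema$outcome_var
  attr(d, "regulator_vars") <- schema$regulator_vars
  attr(d, "nmr_vars") <- schema$nmr_vars
  class(d) <- c("lpl_cohort", "data.frame")
  d
}
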