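#' Run configuration
#'
#' All numeric analysis parameters in one place. Defaults encode the study
#' rules: drug eras merge exposure records of the same class separated by at
#' most 30 uncovered days and must last at least 5 days; systemic
#' glucocorticoid eras under 30 days are steroid bursts, 30 days or more
#' maintenance therapy; cross-class overlaps of at least 30 days (or the full
#' duration of one era) form combination therapy, shorter overlaps a switch;
#' trajectories seen in under 0.5% of the population are pooled; cohort entry
#' requires 365 days of prior observation, 1095 days of follow-up, first
#' diagnosis in 2010-2019, and age 18+ (asthma) or 40+ (COPD).
#'
#' Time is integer day indices (days since 1970-01-01, so `as.Date` integers);
#' intervals are closed and duration = end - start + 1.
#'
#' @param era_gap_days maximum uncovered gap (days) merged inside one era.
#' @param min_era_days minimum era duration kept.
#' @param combination_overlap_days minimum cross-class overlap for combination
#'   therapy (shorter overlaps are switches unless one era is fully covered).
#' @param steroid_maintenance_days duration at or above which a systemic
#'   glucocorticoid era counts as maintenance rather than a burst.
#' @param min_trajectory_fraction retention threshold for aggregated
#'   trajectories, as a fraction of the population.
#' @param prior_observation_days required observation before index.
#' @param followup_days required observation after index.
#' @param asthma_min_age,copd_min_age minimum age at index, in years.
#' @param index_window length-2 integer day-index vector of allowed first
#'   diagnosis dates (default 2010-01-01 to 2019-12-31).
#' @param max_trajectory_depth number of trajectory layers kept.
#' @param truncate_at_index if TRUE, exposures straddling the index day keep
#'   their post-index portion; if FALSE they are used as recorded.
#' @param drop_short_remnants if TRUE, event remnants shorter than
#'   `min_era_days` created by overlap resolution are dropped.
#' @param full_duration_on_remnant if TRUE the "full duration" combination
#'   clause is judged on the current (possibly split) event intervals.
#' @param population_includes_untreated if TRUE the 0.5% retention denominator
#'   is the whole cohort, untreated included.
#' @param other_wedge if TRUE pooled rare trajectories appear as an explicit
#'   "other" wedge in sunburst output.
#' @param seed integer seed recorded with the run.
#' @return A list of class `rx_config`.
#' @export
run_config <- function(era_gap_days = 30L,
                       min_era_days = 5L,
                       combination_overlap_days = 30L,
                       steroid_maintenance_days = 30L,
                       min_trajectory_fraction = 0.005,
                       prior_observation_days = 365L,
                       followup_days = 1095L,
                       asthma_min_age = 18L,
                       copd_min_age = 40L,
                       index_window = as.integer(as.Date(c("2010-01-01",
                                                           "2019-12-31"))),
                       max_trajectory_depth = 5L,
                       truncate_at_index = TRUE,
                       drop_short_remnants = TRUE,
                       full_duration_on_remnant = TRUE,
                       population_includes_untreated = TRUE,
                       other_wedge = TRUE,
                       seed = 1L) {
  cfg <- list(
    era_gap_days = as.integer(era_gap_days),
    min_era_days = as.integer(min_era_days),
    combination_overlap_days = as.integer(combination_overlap_days),
    steroid_maintenance_days = as.integer(steroid_maintenance_days),
    min_trajectory_fraction = min_trajectory_fraction,
    prior_observation_days = as.integer(prior_observation_days),
    followup_days = as.integer(followup_days),
    asthma_min_age = as.integer(asthma_min_age),
    copd_min_age = as.integer(copd_min_age),
    index_window = as.integer(index_window),
    max_trajectory_depth = as.integer(max_trajectory_depth),
    truncate_at_index = isTRUE(truncate_at_index),
    drop_short_remnants = isTRUE(drop_short_remnants),
    full_duration_on_remnant = isTRUE(full_duration_on_remnant),
    population_includes_untreated = isTRUE(population_includes_untreated),
    other_wedge = isTRUE(other_wedge),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "rx_config"
  cfg
}

validate_config <- function(cfg) {
  durs <- c("era_gap_days", "min_era_days", "combination_overlap_days",
            "steroid_maintenance_days", "prior_observation_days",
            "followup_days", "max_trajectory_depth")
  for (d in durs) {
    if (!is.finite(cfg[[d]]) || cfg[[d]] <= 0) {
      stop("config: `", d, "` must be a positive number", call. = FALSE)
    }
  }
  if (!(cfg$min_trajectory_fraction > 0 && cfg$min_trajectory_fraction < 1)) {
    stop("config: `min_trajectory_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (length(cfg$index_window) != 2L ||
      cfg$index_window[1] > cfg$index_window[2]) {
    stop("config: `index_window` must be two ordered day indices",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds any subset of [run_config()]'s arguments by name;
#' `index_window` may be given as two ISO-8601 dates.
#'
#' @param path file path.
#' @return An `rx_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$index_window) && is.character(raw$index_window)) {
    raw$index_window <- as.integer(as.Date(raw$index_window))
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("config: unknown fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Minimum age at index for a disease cohort
#' @param disease "asthma" or "copd".
#' @param config an `rx_config`.
#' @return Integer age in years.
#' @export
min_age_for <- function(disease, config) {
  switch(match.arg(disease, c("asthma", "copd")),
         asthma = config$asthma_min_age,
         copd = config$copd_min_age)
}

day_to_year <- function(day) {
  as.integer(format(as.Date(day, origin = "1970-01-01"), "%Y"))
}
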