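#' First diagnosis day per person
#'
#' Earliest condition-occurrence day for the disease, over all available
#' history. Persons without a diagnosis are simply absent.
#'
#' @param conditions condition_occurrence tibble.
#' @param disease "asthma" or "copd".
#' @return Named integer vector person_id -> day.
#' @export
find_first_diagnosis <- function(conditions, disease) {
  disease <- match.arg(disease, c("asthma", "copd"))
  hit <- conditions[conditions$condition == disease, ]
  if (nrow(hit) == 0) return(stats::setNames(integer(0), character(0)))
  agg <- tapply(hit$day, hit$person_id, min)
  stats::setNames(as.integer(agg), names(agg))
}

#' Exclusion reasons in tally precedence order
#' @return Character vector of reason codes.
#' @export
exclusion_reasons <- function() {
  c("not_in_index_window", "below_min_age", "insufficient_prior_observation",
    "insufficient_followup", "prior_other_disease")
}

#' Build a new-diagnosis cohort with attrition tally
#'
#' Cohort entry (index) is the first diagnosis of the disease. A person is a
#' member when the index date falls in the configured calendar window
#' (2010-2019 by default), age at index (index year minus birth year) meets
#' the disease minimum (18 for asthma, 40 for COPD), at least
#' `prior_observation_days` of observation precede index, at least
#' `followup_days` follow it, and there is no diagnosis of the other disease
#' on or before index (the two cohorts are mutually exclusive by design).
#' Exclusion reasons are tallied with fixed precedence: calendar window,
#' age, prior observation, follow-up, other-disease history.
#'
#' @param b validated `rx_bundle`.
#' @param disease "asthma" or "copd".
#' @param config an `rx_config`.
#' @return List: `cohort` tibble (person_id, disease, index_day,
#'   followup_end_day, age_at_index) and `attrition` tibble (reason, n) with
#'   `diagnosed` and `included` book-end rows.
#' @export
build_cohort <- function(b, disease, config = run_config()) {
  disease <- match.arg(disease, c("asthma", "copd"))
  other <- setdiff(c("asthma", "copd"), disease)
  first_dx <- find_first_diagnosis(b$condition_occurrence, disease)
  first_other <- find_first_diagnosis(b$condition_occurrence, other)

  ids <- names(first_dx)
  op <- b$observation_period
  obs_start <- op$start_day[match(ids, op$person_id)]
  obs_end <- op$end_day[match(ids, op$person_id)]
  birth <- b$person$birth_year[match(ids, b$person$person_id)]
  idx <- unname(first_dx)
  age <- day_to_year(idx) - birth

  in_window <- idx >= config$index_window[1] & idx <= config$index_window[2]
  old_enough <- age >= min_age_for(disease, config)
  prior_ok <- (idx - obs_start) >= config$prior_observation_days
  followup_ok <- (obs_end - idx) >= config$followup_days
  other_idx <- unname(first_other[ids])
  no_other <- is.na(other_idx) | other_idx > idx

  reason <- rep(NA_character_, length(ids))
  reason[!no_other] <- "prior_other_disease"
  reason[!followup_ok] <- "insufficient_followup"
  reason[!prior_ok] <- "insufficient_prior_observation"
  reason[!old_enough] <- "below_min_age"
  reason[!in_window] <- "not_in_index_window"
  included <- is.na(reason)

  cohort <- tibble::tibble(
    person_id = ids[included],
    disease = disease,
    index_day = idx[included],
    followup_end_day = obs_end[included],
    age_at_index = as.integer(age[included])
  )
  cohort <- dplyr::arrange(cohort, .data$person_id)

  tally <- vapply(exclusion_reasons(),
                  function(r) sum(reason == r, na.rm = TRUE), 0L)
  attrition <- tibble::tibble(
    reason = c("diagnosed", exclusion_reasons(), "included"),
    n = c(length(ids), unname(tally), sum(included))
  )
  list(cohort = cohort, attrition = attrition)
}

#' Cohort census: size, percentage male, mean age
#'
#' Persons of unknown sex are excluded from the percentage denominator.
#'
#' @param cohort cohort tibble from [build_cohort()].
#' @param person person table (for sex lookup).
#' @return Tibble (n, pct_male, mean_age), 1-decimal rounding; n = 0 row for
#'   an empty cohort.
#' @export
census <- function(cohort, person) {
  if (nrow(cohort) == 0) {
    return(tibble::tibble(n = 0L, pct_male = NA_real_, mean_age = NA_real_))
  }
  sex <- person$sex[match(cohort$person_id, person$person_id)]
  known <- sex %in% c("male", "female")
  tibble::tibble(
    n = nrow(cohort),
    pct_male = if (any(known)) round(100 * mean(sex[known] == "male"), 1)
               else NA_real_,
    mean_age = round(mean(cohort$age_at_index), 1)
  )
}
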