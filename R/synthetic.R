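#' Scenario configuration for the synthetic-data generator
#'
#' Describes a simulated source population: cohort disease, planted
#' treatment trajectories with their probabilities, exposure recording style
#' (EHR-like `prescription` records spanning whole treatment periods, or
#' claims-like `dispensing` fills of ~30 days with stochastic refill gaps),
#' an untreated fraction, fractions of deliberately ineligible persons, and
#' comorbidity prevalences.
#'
#' The generator guarantees that planted structure is recoverable under the
#' default analysis rules: gaps between distinct planted events always
#' exceed the era gap (so eras do not merge across events), refill gaps
#' within an event never exceed it (so fills merge into one era), and
#' multi-class events are planted with identical class intervals (full
#' overlap, hence combination therapy by the full-duration rule).
#'
#' @param n_persons number of persons to generate.
#' @param disease "asthma" or "copd".
#' @param untreated_fraction fraction of eligible persons with no exposures.
#' @param trajectory_distribution list of `list(sequence = list(<class
#'   vectors>), prob = , transition = )`; probabilities must sum to 1.
#'   `transition` (optional) records the designed first-transition category.
#' @param exposure_style "prescription" or "dispensing".
#' @param dispensing_fill_days nominal days covered per dispensing fill.
#' @param dispensing_gap_mean,dispensing_gap_sd refill-gap distribution
#'   (days), clamped to `[0, era_gap_days]`.
#' @param event_duration_mean,event_duration_sd planted event duration
#'   (days), clamped to `[30, 365]`.
#' @param inter_event_gap_mean,inter_event_gap_sd gap between planted events
#'   (days), clamped to `(era_gap_days, 365]`.
#' @param ineligible_fractions named fractions for `too_young`,
#'   `short_prior_obs`, `short_followup`, `prior_other_disease`.
#' @param comorbidity_prevalences named probabilities per condition concept.
#' @param seed generator seed.
#' @return A list of class `rx_scenario`.
#' @export
scenario_config <- function(n_persons = 1000L,
                            disease = c("asthma", "copd"),
                            untreated_fraction = 0.2,
                            trajectory_distribution = default_trajectories(),
                            exposure_style = c("prescription", "dispensing"),
                            dispensing_fill_days = 30L,
                            dispensing_gap_mean = 10,
                            dispensing_gap_sd = 5,
                            event_duration_mean = 120,
                            event_duration_sd = 30,
                            inter_event_gap_mean = 90,
                            inter_event_gap_sd = 30,
                            ineligible_fractions = c(too_young = 0,
                                                     short_prior_obs = 0,
                                                     short_followup = 0,
                                                     prior_other_disease = 0),
                            comorbidity_prevalences = c(anxiety = 0.2,
                                                        diabetes = 0.1),
                            seed = 1L) {
  sc <- list(
    n_persons = as.integer(n_persons),
    disease = match.arg(disease),
    untreated_fraction = untreated_fraction,
    trajectory_distribution = trajectory_distribution,
    exposure_style = match.arg(exposure_style),
    dispensing_fill_days = as.integer(dispensing_fill_days),
    dispensing_gap_mean = dispensing_gap_mean,
    dispensing_gap_sd = dispensing_gap_sd,
    event_duration_mean = event_duration_mean,
    event_duration_sd = event_duration_sd,
    inter_event_gap_mean = inter_event_gap_mean,
    inter_event_gap_sd = inter_event_gap_sd,
    ineligible_fractions = ineligible_fractions,
    comorbidity_prevalences = comorbidity_prevalences,
    seed = as.integer(seed)
  )
  class(sc) <- "rx_scenario"
  sc
}

#' Default planted trajectory mix (asthma-flavoured)
#' @return Trajectory distribution list for [scenario_config()].
#' @export
default_trajectories <- function() {
  list(
    list(sequence = list("SABA"), prob = 0.35),
    list(sequence = list("SABA", "ICS"), prob = 0.25),
    list(sequence = list("SABA", "LABA-ICS"), prob = 0.15),
    list(sequence = list("ICS"), prob = 0.10),
    list(sequence = list("SABA", "steroid_burst"), prob = 0.10),
    list(sequence = list("SABA", c("ICS", "SABA")), prob = 0.05)
  )
}

#' Trajectory distribution realising a designed first-transition mix
#'
#' Maps transition categories to canonical two-event sequences so the
#' planted first transition is the category itself: step-up is rescue to
#' fixed combination, a steroid burst in second position starts an
#' exacerbation, and so on.
#'
#' @param mix named probabilities over transition categories (must sum
#'   to 1); supported names: step_up, step_down, switching,
#'   exacerbation_start, exacerbation_end, no_followup.
#' @return Trajectory distribution list for [scenario_config()].
#' @export
transition_scenario <- function(mix) {
  canned <- list(
    step_up = list("SABA", "LABA-ICS"),
    step_down = list("LABA-ICS", "ICS"),
    switching = list("ICS", "LTRA"),
    exacerbation_start = list("SABA", "steroid_burst"),
    exacerbation_end = list("steroid_burst", "SABA"),
    no_followup = list("SABA")
  )
  unknown <- setdiff(names(mix), names(canned))
  if (length(unknown) > 0) {
    stop("transition_scenario: unsupported categories: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lapply(names(mix), function(k) {
    list(sequence = canned[[k]], prob = unname(mix[[k]]), transition = k)
  })
}

validate_scenario <- function(sc, config) {
  probs <- vapply(sc$trajectory_distribution, `[[`, 0, "prob")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("scenario: trajectory probabilities must sum to 1", call. = FALSE)
  }
  fr <- c(sc$untreated_fraction, sc$ineligible_fractions,
          sc$comorbidity_prevalences)
  if (any(fr < 0 | fr > 1)) {
    stop("scenario: all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(sc$ineligible_fractions) > 1) {
    stop("scenario: ineligible fractions sum above 1", call. = FALSE)
  }
  if (sc$event_duration_mean < config$min_era_days) {
    stop("scenario: event duration below the minimum era duration is ",
         "infeasible", call. = FALSE)
  }
  if (sc$inter_event_gap_mean <= config$era_gap_days) {
    stop("scenario: inter-event gap mean must exceed era_gap_days or ",
         "planted events would merge", call. = FALSE)
  }
  for (td in sc$trajectory_distribution) {
    sets <- lapply(td$sequence, function(s) sort(unique(s)))
    bad <- setdiff(unlist(sets), era_classes())
    if (length(bad) > 0) {
      stop("scenario: unknown class in planted sequence: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(sets) > 1) {
      for (k in 2:length(sets)) {
        if (identical(sets[[k - 1]], sets[[k]])) {
          stop("scenario: consecutive identical class sets in a planted ",
               "sequence are unrecoverable", call. = FALSE)
        }
      }
    }
  }
  invisible(sc)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# exposure class recorded in the raw table for a planted era-level class
raw_class <- function(cls) {
  ifelse(cls %in% c("steroid_burst", "steroid_maintenance"),
         "systemic_glucocorticoid", cls)
}

#' Generate synthetic OMOP-subset tables with ground truth
#'
#' Every generated person receives a first diagnosis of the scenario
#' disease; fractions of them are made ineligible for a specific single
#' reason (too young, short prior observation, short follow-up, prior
#' diagnosis of the other disease). Eligible persons are untreated with the
#' configured probability, otherwise they receive one planted trajectory
#' drawn from the scenario distribution, realised as prescription- or
#' dispensing-style exposure records.
#'
#' @param scenario an `rx_scenario`.
#' @param config an `rx_config` (analysis rules the generator must respect).
#' @return List: validated `bundle` and `ground_truth` tibble (person_id,
#'   eligible, reason, treated, trajectory, n_events, planted_transition).
#' @export
generate_scenario <- function(scenario, config = run_config()) {
  validate_scenario(scenario, config)
  withr::with_seed(scenario$seed, generate_impl(scenario, config))
}

generate_impl <- function(sc, config) {
  n <- sc$n_persons
  disease <- sc$disease
  other <- setdiff(c("asthma", "copd"), disease)
  min_age <- min_age_for(disease, config)

  ids <- sprintf("P%06d", seq_len(n))
  frac <- sc$ineligible_fractions
  states <- c(names(frac), "eligible")
  pstate <- c(unname(frac), 1 - sum(frac))
  state <- sample(states, n, replace = TRUE, prob = pstate)

  probs <- vapply(sc$trajectory_distribution, `[[`, 0, "prob")
  traj_idx <- ifelse(state == "eligible" &
                       stats::runif(n) >= sc$untreated_fraction,
                     sample.int(length(probs), n, replace = TRUE,
                                prob = probs),
                     NA_integer_)

  # leave room so even long planted trajectories end inside the window-end
  index_day <- sample(config$index_window[1]:config$index_window[2], n,
                      replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)

  age <- ifelse(state == "too_young",
                sample(max(1L, min_age - 15L):(min_age - 1L), n,
                       replace = TRUE),
                sample((min_age + 5L):80L, n, replace = TRUE))
  birth_year <- day_to_year(index_day) - age

  obs_start <- index_day - config$prior_observation_days -
    sample(0:730, n, replace = TRUE)
  short_prior <- state == "short_prior_obs"
  obs_start[short_prior] <- index_day[short_prior] -
    sample(0:(config$prior_observation_days - 1L), sum(short_prior),
           replace = TRUE)

  persons <- tibble::tibble(person_id = ids, birth_year = birth_year,
                            sex = sex)

  cond_rows <- list(tibble::tibble(person_id = ids, condition = disease,
                                   day = index_day))
  prior_oth <- state == "prior_other_disease"
  if (any(prior_oth)) {
    lag <- sample(1:200, sum(prior_oth), replace = TRUE)
    d <- pmax(index_day[prior_oth] - lag, obs_start[prior_oth])
    cond_rows[[length(cond_rows) + 1L]] <-
      tibble::tibble(person_id = ids[prior_oth], condition = other, day = d)
  }
  for (cm in names(sc$comorbidity_prevalences)) {
    has <- stats::runif(n) < sc$comorbidity_prevalences[[cm]]
    has <- has & (index_day - obs_start >= 2)
    if (!any(has)) next
    lo <- if (cm == "lower_respiratory_tract_infection") {
      pmax(obs_start[has], index_day[has] - 365L)
    } else {
      obs_start[has]
    }
    hi <- index_day[has] - 1L
    d <- lo + floor(stats::runif(sum(has)) * (hi - lo + 1))
    cond_rows[[length(cond_rows) + 1L]] <-
      tibble::tibble(person_id = ids[has], condition = cm, day = as.integer(d))
  }

  ex_rows <- list()
  gt_traj <- character(n)
  gt_nev <- integer(n)
  gt_trans <- rep(NA_character_, n)
  last_end <- index_day  # day treatment activity finishes, per person

  for (i in seq_len(n)) {
    if (is.na(traj_idx[i])) next
    td <- sc$trajectory_distribution[[traj_idx[i]]]
    sets <- lapply(td$sequence, function(s) sort(unique(s)))
    labels <- vapply(sets, canonical_label, "")
    gt_traj[i] <- paste(labels, collapse = "|")
    gt_nev[i] <- length(sets)
    gt_trans[i] <- if (!is.null(td$transition)) td$transition
                   else NA_character_

    s <- index_day[i] + sample(0:60, 1)
    for (k in seq_along(sets)) {
      set <- sets[[k]]
      dur <- if ("steroid_burst" %in% set) {
        sample(max(config$min_era_days, 5L):29L, 1)
      } else if ("steroid_maintenance" %in% set) {
        sample(30:90, 1)
      } else {
        as.integer(clamp(round(stats::rnorm(1, sc$event_duration_mean,
                                            sc$event_duration_sd)), 30, 365))
      }
      e <- s + dur - 1L
      for (cls in set) {
        rc <- raw_class(cls)
        if (sc$exposure_style == "prescription") {
          ex_rows[[length(ex_rows) + 1L]] <-
            tibble::tibble(person_id = ids[i], drug_class = rc,
                           start_day = as.integer(s), end_day = as.integer(e))
        } else {
          cur <- s
          while (cur <= e) {
            fe <- min(cur + sc$dispensing_fill_days - 1L, e)
            ex_rows[[length(ex_rows) + 1L]] <-
              tibble::tibble(person_id = ids[i], drug_class = rc,
                             start_day = as.integer(cur),
                             end_day = as.integer(fe))
            gap <- as.integer(clamp(round(stats::rnorm(
              1, sc$dispensing_gap_mean, sc$dispensing_gap_sd)),
              0, config$era_gap_days))
            cur <- fe + 1L + gap
          }
        }
      }
      last_end[i] <- e
      if (k < length(sets)) {
        gap <- as.integer(clamp(round(stats::rnorm(
          1, sc$inter_event_gap_mean, sc$inter_event_gap_sd)),
          config$era_gap_days + 1L, 365))
        s <- e + 1L + gap
      }
    }
  }

  obs_end <- pmax(index_day + config$followup_days,
                  last_end + config$era_gap_days + 1L) +
    sample(0:365, n, replace = TRUE)
  short_fu <- state == "short_followup"
  obs_end[short_fu] <- index_day[short_fu] +
    sample(0:(config$followup_days - 1L), sum(short_fu), replace = TRUE)

  conditions <- dplyr::bind_rows(cond_rows)
  # comorbidity days were drawn before obs_end was final; all lie <= index
  exposures <- if (length(ex_rows) > 0) dplyr::bind_rows(ex_rows) else
    tibble::tibble(person_id = character(0), drug_class = character(0),
                   start_day = integer(0), end_day = integer(0))

  b <- bundle(
    person = persons,
    observation_period = tibble::tibble(person_id = ids,
                                        start_day = as.integer(obs_start),
                                        end_day = as.integer(obs_end)),
    condition_occurrence = conditions,
    drug_exposure = exposures
  )

  gt <- tibble::tibble(
    person_id = ids,
    eligible = state == "eligible",
    reason = ifelse(state == "eligible", "eligible", state),
    treated = !is.na(traj_idx),
    trajectory = gt_traj,
    n_events = gt_nev,
    planted_transition = gt_trans
  )
  list(bundle = b, ground_truth = gt)
}

#' Build a deterministic single-person bundle for worked examples
#'
#' @param obs length-2 vector: observation period start and end day.
#' @param conditions list of `list(condition =, day =)` entries (or a
#'   tibble with those columns).
#' @param exposures list of `list(drug_class =, start_day =, end_day =)`
#'   entries (or a tibble).
#' @param birth_year,sex,person_id person attributes.
#' @return A validated `rx_bundle` with one person.
#' @export
make_toy_patient <- function(obs, conditions = list(), exposures = list(),
                             birth_year = 1970L, sex = "female",
                             person_id = "P1") {
  as_tbl <- function(x, cols) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    if (length(x) == 0) {
      return(tibble::as_tibble(stats::setNames(
        rep(list(vector(mode = "integer", 0L)), length(cols)), cols)))
    }
    dplyr::bind_rows(lapply(x, tibble::as_tibble))
  }
  co <- as_tbl(conditions, c("condition", "day"))
  if (nrow(co) > 0) co$person_id <- person_id else co <-
    tibble::tibble(person_id = character(0), condition = character(0),
                   day = integer(0))
  dx <- as_tbl(exposures, c("drug_class", "start_day", "end_day"))
  if (nrow(dx) > 0) dx$person_id <- person_id else dx <-
    tibble::tibble(person_id = character(0), drug_class = character(0),
                   start_day = integer(0), end_day = integer(0))
  bundle(
    person = tibble::tibble(person_id = person_id,
                            birth_year = as.integer(birth_year), sex = sex),
    observation_period = tibble::tibble(person_id = person_id,
                                        start_day = as.integer(obs[1]),
                                        end_day = as.integer(obs[2])),
    condition_occurrence = co,
    drug_exposure = dx
  )
}
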