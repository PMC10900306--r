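#' Run the full trajectory analysis for one cohort
#'
#' End-to-end: build the disease cohort (and the other-disease cohort, to
#' assert mutual exclusivity), construct post-index drug eras, resolve
#' overlaps into treatment events, assemble trajectories, aggregate counts
#' with the 0.5% retention rule, classify first transitions on the
#' guideline ladder, and compute baseline characteristics.
#'
#' Structural invariants are asserted on every run: the asthma and COPD
#' cohorts share no person, retained + pooled + untreated counts equal the
#' cohort size, and broad-transition percentages sum to 100 within
#' rounding.
#'
#' @param b validated `rx_bundle`.
#' @param disease "asthma" or "copd".
#' @param config an `rx_config`.
#' @param ladder an `rx_ladder`; defaults to the shipped ladder for
#'   `disease`.
#' @return A named list of results (cohort, attrition, eras, events,
#'   trajectories, trajectory_counts, sunburst, transition_table,
#'   conformance_pct, first_line, baseline, census, percent_treated,
#'   n_cohort).
#' @export
run_pipeline <- function(b, disease, config = run_config(),
                         ladder = default_ladder(disease)) {
  disease <- match.arg(disease, c("asthma", "copd"))
  other <- setdiff(c("asthma", "copd"), disease)

  built <- build_cohort(b, disease, config)
  built_other <- build_cohort(b, other, config)
  overlap <- intersect(built$cohort$person_id, built_other$cohort$person_id)
  if (length(overlap) > 0) {
    stop("invariant violated: asthma and COPD cohorts share person(s): ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  cohort <- built$cohort

  index_days <- stats::setNames(cohort$index_day, cohort$person_id)
  eras <- build_eras(b$drug_exposure, config, index_days = index_days)
  events <- resolve_all_events(eras, config)
  trajectories <- build_trajectories(events, cohort$person_id, config)

  counted <- count_trajectories(trajectories, config)
  if (config$population_includes_untreated) {
    total <- sum(counted$counts$n) + counted$other_count +
      counted$untreated_count
    if (total != nrow(cohort)) {
      stop("invariant violated: retained + other + untreated (", total,
           ") != cohort size (", nrow(cohort), ")", call. = FALSE)
    }
  }
  tree <- to_sunburst(counted, config)

  trans <- transition_table(trajectories, ladder)
  if (nrow(trans) > 0 && abs(sum(trans$pct) - 100) > 0.2) {
    stop("invariant violated: transition percentages sum to ",
         sum(trans$pct), call. = FALSE)
  }

  pct_tr <- percent_treated(trajectories)

  depth <- config$max_trajectory_depth
  traj_flat <- trajectories[c("person_id", "treated", "trajectory")]
  labs <- strsplit(trajectories$trajectory, "|", fixed = TRUE)
  for (d in seq_len(depth)) {
    traj_flat[[paste0("label_", d)]] <-
      vapply(labs, function(l) if (length(l) >= d) l[d] else NA_character_,
             "")
  }

  counts_flat <- counted$counts
  counts_flat <- dplyr::bind_rows(
    counts_flat,
    tibble::tibble(trajectory = c("(other)", "(untreated)"),
                   n = c(counted$other_count, counted$untreated_count),
                   fraction = c(counted$other_count, counted$untreated_count) /
                     max(counted$population, 1L)))

  list(
    disease = disease,
    cohort = cohort,
    attrition = built$attrition,
    eras = eras,
    events = events[c("person_id", "ordinal", "label", "start_day",
                      "end_day")],
    trajectories = trajectories,
    trajectory_table = traj_flat,
    counted = counted,
    trajectory_counts = counts_flat,
    sunburst = tree,
    transition_table = trans,
    conformance_pct = guideline_conformance(trajectories, ladder),
    first_line = first_line_distribution(trajectories),
    baseline = baseline_table(cohort, b),
    census = census(cohort, b$person),
    percent_treated = pct_tr,
    n_cohort = nrow(cohort)
  )
}
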