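#' Collapse raw exposures into drug eras
#'
#' Within each person and drug class, exposure intervals are unioned and
#' neighbouring intervals separated by at most `era_gap_days` uncovered days
#' are merged into one continuous era (the gap between closed intervals
#' [a1,b1] and [a2,b2] is a2 - b1 - 1). Eras shorter than `min_era_days` are
#' dropped *after* merging, so chains of short fills survive.
#'
#' When `index_days` is supplied (a named day-index vector keyed by
#' person_id), only treatment from the index day onwards is considered:
#' exposures ending before index are removed and exposures straddling it are
#' truncated at index when `config$truncate_at_index` is TRUE (otherwise kept
#' whole). Persons absent from `index_days` are dropped.
#'
#' @param exposures drug_exposure tibble (person_id, drug_class, start_day,
#'   end_day), validated.
#' @param config an `rx_config`.
#' @param index_days optional named integer vector person_id -> index day.
#' @return Tibble (person_id, drug_class, start_day, end_day, duration_days),
#'   sorted by person, class, start; systemic glucocorticoid eras are already
#'   split into `steroid_burst` / `steroid_maintenance` via
#'   [classify_steroids()].
#' @export
build_eras <- function(exposures, config = run_config(), index_days = NULL) {
  ex <- tibble::as_tibble(exposures)
  if (!is.null(index_days)) {
    idx <- index_days[ex$person_id]
    keep <- !is.na(idx) & ex$end_day >= idx
    ex <- ex[keep, ]
    idx <- idx[keep]
    if (config$truncate_at_index && nrow(ex) > 0) {
      ex$start_day <- pmax(ex$start_day, unname(idx))
    } else if (!config$truncate_at_index) {
      # use records as recorded, but still require post-index overlap (above)
    }
  }
  empty <- tibble::tibble(person_id = character(0), drug_class = character(0),
                          start_day = integer(0), end_day = integer(0),
                          duration_days = integer(0))
  if (nrow(ex) == 0) return(empty)

  ex <- dplyr::arrange(ex, .data$person_id, .data$drug_class,
                       .data$start_day, .data$end_day)
  out <- dplyr::group_modify(
    dplyr::group_by(ex, .data$person_id, .data$drug_class),
    function(g, key) merge_intervals(g$start_day, g$end_day,
                                     config$era_gap_days)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::mutate(out,
                       duration_days = .data$end_day - .data$start_day + 1L)
  out <- dplyr::filter(out, .data$duration_days >= config$min_era_days)
  out <- dplyr::arrange(out, .data$person_id, .data$drug_class,
                        .data$start_day)
  classify_steroids(out, config)
}

# Merge sorted closed intervals, closing gaps <= gap_days.
merge_intervals <- function(start, end, gap_days) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  res_s <- integer(0); res_e <- integer(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] - me - 1L <= gap_days) {
        me <- max(me, end[i])
      } else {
        res_s <- c(res_s, ms); res_e <- c(res_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  tibble::tibble(start_day = as.integer(c(res_s, ms)),
                 end_day = as.integer(c(res_e, me)))
}

#' Split systemic glucocorticoid eras into burst vs maintenance
#'
#' A systemic glucocorticoid era shorter than
#' `config$steroid_maintenance_days` (default 30) is relabelled
#' `steroid_burst` — the marker of an acute exacerbation — and one of 30 days
#' or more `steroid_maintenance`. The merged era's duration decides, not the
#' individual records'. Other classes pass through unchanged.
#'
#' @param eras era tibble from [build_eras()].
#' @param config an `rx_config`.
#' @return Era tibble with `drug_class` in [era_classes()].
#' @export
classify_steroids <- function(eras, config = run_config()) {
  sys <- eras$drug_class == "systemic_glucocorticoid"
  dur <- eras$end_day - eras$start_day + 1L
  eras$drug_class[sys] <- ifelse(dur[sys] >= config$steroid_maintenance_days,
                                 "steroid_maintenance", "steroid_burst")
  eras
}
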