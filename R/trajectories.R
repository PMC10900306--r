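#' Resolve one person's drug eras into a sequence of treatment events
#'
#' Eras of different classes may overlap in time. Overlaps are resolved
#' iteratively, always taking the overlapping pair whose overlap starts
#' earliest (ties: longer event first, then alphabetical label):
#'
#' * overlap of at least `combination_overlap_days`, or covering the full
#'   duration of one of the two events, becomes a combination event over the
#'   overlap carrying the union of the class sets; the non-overlapping
#'   remnants stay behind as events;
#' * a shorter overlap is a switch: the earlier event is truncated the day
#'   before the later one starts.
#'
#' Two overlapping events with identical class sets are merged outright.
#' After resolution, remnants shorter than `min_era_days` are dropped (when
#' `config$drop_short_remnants`) and consecutive events with identical class
#' sets are merged.
#'
#' @param eras era tibble for a single person (person_id, drug_class,
#'   start_day, end_day).
#' @param config an `rx_config`.
#' @return Tibble (person_id, ordinal, label, classes, start_day, end_day);
#'   `classes` is a list-column of class-name vectors.
#' @export
resolve_events <- function(eras, config = run_config()) {
  empty <- tibble::tibble(person_id = character(0), ordinal = integer(0),
                          label = character(0), classes = list(),
                          start_day = integer(0), end_day = integer(0))
  if (nrow(eras) == 0) return(empty)
  pid <- unique(eras$person_id)
  stopifnot(length(pid) == 1L)

  ev <- lapply(seq_len(nrow(eras)), function(i) {
    list(classes = eras$drug_class[i],
         start = eras$start_day[i], end = eras$end_day[i])
  })

  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10000L) stop("resolve_events: failed to converge",
                             call. = FALSE)
    pick <- find_overlap_pair(ev)
    if (is.null(pick)) break
    ev <- resolve_pair(ev, pick$i, pick$j, config)
  }

  if (config$drop_short_remnants) {
    ev <- Filter(function(e) e$end - e$start + 1L >= config$min_era_days, ev)
  }
  if (length(ev) == 0) return(empty)
  ev <- ev[order(vapply(ev, `[[`, 0L, "start"))]

  # merge consecutive events holding an identical class set
  merged <- list(ev[[1]])
  if (length(ev) > 1) {
    for (k in 2:length(ev)) {
      last <- merged[[length(merged)]]
      if (setequal(last$classes, ev[[k]]$classes)) {
        last$end <- max(last$end, ev[[k]]$end)
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- ev[[k]]
      }
    }
  }

  tibble::tibble(
    person_id = pid,
    ordinal = seq_along(merged),
    label = vapply(merged, function(e) canonical_label(e$classes), ""),
    classes = lapply(merged, function(e) sort(unique(e$classes))),
    start_day = vapply(merged, function(e) as.integer(e$start), 0L),
    end_day = vapply(merged, function(e) as.integer(e$end), 0L)
  )
}

# earliest-starting overlap; ties: longer event first, then alphabetical label
find_overlap_pair <- function(ev) {
  n <- length(ev)
  if (n < 2) return(NULL)
  best <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      os <- max(ev[[i]]$start, ev[[j]]$start)
      oe <- min(ev[[i]]$end, ev[[j]]$end)
      if (oe < os) next
      len <- max(ev[[i]]$end - ev[[i]]$start,
                 ev[[j]]$end - ev[[j]]$start) + 1L
      lab <- min(canonical_label(ev[[i]]$classes),
                 canonical_label(ev[[j]]$classes))
      cand <- list(i = i, j = j, os = os, len = len, lab = lab)
      if (is.null(best) ||
          cand$os < best$os ||
          (cand$os == best$os && cand$len > best$len) ||
          (cand$os == best$os && cand$len == best$len && cand$lab < best$lab)) {
        best <- cand
      }
    }
  }
  best
}

resolve_pair <- function(ev, i, j, config) {
  a <- ev[[i]]; b <- ev[[j]]
  # A = earlier start; ties: longer; then alphabetical label
  swap <- (b$start < a$start) ||
    (b$start == a$start && (b$end - b$start) > (a$end - a$start)) ||
    (b$start == a$start && (b$end - b$start) == (a$end - a$start) &&
       canonical_label(b$classes) < canonical_label(a$classes))
  if (swap) { tmp <- a; a <- b; b <- tmp }

  os <- max(a$start, b$start)
  oe <- min(a$end, b$end)
  ov <- oe - os + 1L
  rest <- ev[-c(i, j)]

  if (setequal(a$classes, b$classes)) {
    return(c(rest, list(list(classes = a$classes,
                             start = min(a$start, b$start),
                             end = max(a$end, b$end)))))
  }

  dur_a <- a$end - a$start + 1L
  dur_b <- b$end - b$start + 1L
  combo <- ov >= config$combination_overlap_days ||
    ov == dur_a || ov == dur_b

  if (combo) {
    new <- list(list(classes = sort(unique(c(a$classes, b$classes))),
                     start = os, end = oe))
    if (a$start < os) {
      new <- c(new, list(list(classes = a$classes, start = a$start,
                              end = os - 1L)))
    }
    if (a$end > oe) {
      new <- c(new, list(list(classes = a$classes, start = oe + 1L,
                              end = a$end)))
    }
    if (b$end > oe) {
      new <- c(new, list(list(classes = b$classes, start = oe + 1L,
                              end = b$end)))
    }
    c(rest, new)
  } else {
    # switch: later class wins the overlap window
    new <- list(b)
    if (b$start - 1L >= a$start) {
      new <- c(new, list(list(classes = a$classes, start = a$start,
                              end = b$start - 1L)))
    }
    c(rest, new)
  }
}

#' Resolve events for every person in an era table
#'
#' @param eras era tibble (any number of persons).
#' @param config an `rx_config`.
#' @return Row-bound [resolve_events()] output.
#' @export
resolve_all_events <- function(eras, config = run_config()) {
  if (nrow(eras) == 0) return(resolve_events(eras, config))
  parts <- split(eras, eras$person_id)
  dplyr::bind_rows(lapply(parts, resolve_events, config = config))
}

#' Build a patient's treatment trajectory from resolved events
#'
#' The trajectory is the ordered sequence of distinct event labels:
#' consecutive duplicate labels are merged and the sequence is truncated at
#' `config$max_trajectory_depth` layers. A patient with no events is
#' untreated (empty label sequence).
#'
#' @param events [resolve_events()] output for one person.
#' @param config an `rx_config`.
#' @return List with `person_id`, `treated` flag and `labels` character
#'   vector.
#' @export
build_trajectory <- function(events, config = run_config()) {
  if (nrow(events) == 0) {
    return(list(person_id = NA_character_, treated = FALSE,
                labels = character(0)))
  }
  labs <- events$label[order(events$ordinal)]
  labs <- rle(labs)$values
  labs <- utils::head(labs, config$max_trajectory_depth)
  list(person_id = events$person_id[1], treated = TRUE, labels = labs)
}

#' Trajectories for a whole cohort
#'
#' One row per cohort member, untreated members included with an empty
#' trajectory.
#'
#' @param events resolved events table (all persons).
#' @param cohort_ids character vector of cohort person_ids.
#' @param config an `rx_config`.
#' @return Tibble (person_id, treated, trajectory, labels list-column).
#' @export
build_trajectories <- function(events, cohort_ids, config = run_config()) {
  if (length(cohort_ids) == 0) {
    return(tibble::tibble(person_id = character(0), treated = logical(0),
                          trajectory = character(0), labels = list()))
  }
  parts <- split(events, events$person_id)
  rows <- lapply(cohort_ids, function(pid) {
    if (!is.null(parts[[pid]])) {
      tr <- build_trajectory(parts[[pid]], config)
      tibble::tibble(person_id = pid, treated = TRUE,
                     trajectory = paste(tr$labels, collapse = "|"),
                     labels = list(tr$labels))
    } else {
      tibble::tibble(person_id = pid, treated = FALSE, trajectory = "",
                     labels = list(character(0)))
    }
  })
  dplyr::bind_rows(rows)
}

#' Percentage of cohort members receiving any respiratory drug
#'
#' @param trajectories [build_trajectories()] output.
#' @return Percentage (1 decimal); `NA` for an empty cohort.
#' @export
percent_treated <- function(trajectories) {
  if (nrow(trajectories) == 0) return(NA_real_)
  round(100 * mean(trajectories$treated), 1)
}
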