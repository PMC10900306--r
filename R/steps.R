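#' Guideline-derived treatment intensity ladders
#'
#' A ladder maps canonical event labels to integer intensity levels and
#' carries the allowed transitions of the strict guideline reading. The
#' defaults shipped under `inst/extdata` are reconstructions of the GINA
#' (asthma) and GOLD (COPD) step structures and are data, not code: they are
#' meant to be reviewed and edited before conformance numbers are
#' interpreted.
#'
#' Level lookup for a label: the explicit `levels` map first; otherwise any
#' member class listed under `level_rules` forces that level (e.g. biologics
#' or maintenance steroids = 5); otherwise rescue-only sets are level 1 and
#' sets that reduce to a mapped label after dropping rescue classes inherit
#' its level; anything else is unclassified.
#'
#' @param disease "asthma" or "copd".
#' @param path optional YAML file overriding the shipped default.
#' @return A list of class `rx_ladder`.
#' @export
default_ladder <- function(disease, path = NULL) {
  disease <- match.arg(disease, c("asthma", "copd"))
  if (is.null(path)) {
    path <- system.file("extdata", paste0("ladder_", disease, ".yaml"),
                        package = "airpaths")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("no ladder definition found for disease: ", disease, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  ladder <- list(
    disease = raw$disease %||% disease,
    levels = vapply(raw$levels, as.integer, 0L),
    level_rules = vapply(raw$level_rules, as.integer, 0L),
    rescue_classes = as.character(raw$rescue_classes),
    strict_transitions = lapply(raw$strict_transitions, as.character)
  )
  class(ladder) <- "rx_ladder"
  ladder
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intensity level of a canonical event label
#' @param label canonical label.
#' @param ladder an `rx_ladder`.
#' @return Integer level, or `NA` when unclassified.
#' @export
ladder_level <- function(label, ladder) {
  if (label %in% names(ladder$levels)) return(ladder$levels[[label]])
  classes <- label_classes(label)
  ruled <- intersect(classes, names(ladder$level_rules))
  if (length(ruled) > 0) return(max(ladder$level_rules[ruled]))
  non_rescue <- setdiff(classes, ladder$rescue_classes)
  if (length(non_rescue) == 0) return(1L)
  if (length(non_rescue) < length(classes)) {
    return(ladder_level(canonical_label(non_rescue), ladder))
  }
  NA_integer_
}

#' Fixed reporting order of the broad transition categories
#' @return Character vector of the seven category names.
#' @export
transition_categories <- function() {
  c("step_up", "step_down", "switching", "exacerbation_start",
    "exacerbation_end", "no_followup", "other")
}

#' Classify one first-to-second treatment transition (broad definition)
#'
#' Precedence: no second treatment is `no_followup`; a steroid burst
#' appearing in the second event but not the first marks the start of an
#' acute exacerbation, the reverse its end; otherwise ladder levels decide
#' step-up / step-down, equal levels with different labels are switching,
#' and transitions involving an unclassifiable label are `other`. When both
#' events contain a burst, the burst is transparent: the non-burst members
#' are compared.
#'
#' @param first_label canonical label of the first event.
#' @param second_label canonical label of the second event, or `NA`/`""`.
#' @param ladder an `rx_ladder`.
#' @return One of [transition_categories()].
#' @export
classify_transition <- function(first_label, second_label, ladder) {
  if (!inherits(ladder, "rx_ladder")) {
    stop("classify_transition: `ladder` must be an rx_ladder", call. = FALSE)
  }
  if (is.null(second_label) || is.na(second_label) ||
      !nzchar(second_label)) {
    return("no_followup")
  }
  c1 <- label_classes(first_label)
  c2 <- label_classes(second_label)
  b1 <- "steroid_burst" %in% c1
  b2 <- "steroid_burst" %in% c2
  if (b2 && !b1) return("exacerbation_start")
  if (b1 && !b2) return("exacerbation_end")
  if (b1 && b2) {
    c1 <- setdiff(c1, "steroid_burst")
    c2 <- setdiff(c2, "steroid_burst")
    if (length(c1) == 0 || length(c2) == 0) return("other")
    first_label <- canonical_label(c1)
    second_label <- canonical_label(c2)
  }
  l1 <- ladder_level(first_label, ladder)
  l2 <- ladder_level(second_label, ladder)
  if (is.na(l1) || is.na(l2)) return("other")
  if (l2 > l1) return("step_up")
  if (l2 < l1) return("step_down")
  if (!identical(first_label, second_label)) return("switching")
  "other"
}

#' First transition per treated patient
#'
#' @param trajectories [build_trajectories()] output.
#' @param ladder an `rx_ladder`.
#' @return Tibble (person_id, first, second, category) over treated members.
#' @export
classify_first_transitions <- function(trajectories, ladder) {
  tr <- trajectories[trajectories$treated, ]
  if (nrow(tr) == 0) {
    return(tibble::tibble(person_id = character(0), first = character(0),
                          second = character(0), category = character(0)))
  }
  first <- vapply(tr$labels, function(l) l[1], "")
  second <- vapply(tr$labels, function(l) {
    if (length(l) >= 2) l[2] else NA_character_
  }, "")
  category <- mapply(classify_transition, first, second,
                     MoreArgs = list(ladder = ladder), USE.NAMES = FALSE)
  tibble::tibble(person_id = tr$person_id, first = first, second = second,
                 category = as.character(category))
}

#' Broad-definition transition table (seven fixed categories)
#'
#' Percentage of treated patients per transition category, in the fixed
#' reporting order step-up, step-down, switching, start/end of acute
#' exacerbation, no follow-up treatment, other. Percentages use the treated
#' count as denominator and sum to 100 up to rounding.
#'
#' @param trajectories [build_trajectories()] output.
#' @param ladder an `rx_ladder`.
#' @return Tibble (category, n, pct); zero rows when no member is treated.
#' @export
transition_table <- function(trajectories, ladder) {
  cls <- classify_first_transitions(trajectories, ladder)
  if (nrow(cls) == 0) {
    return(tibble::tibble(category = character(0), n = integer(0),
                          pct = numeric(0)))
  }
  n <- vapply(transition_categories(),
              function(k) sum(cls$category == k), 0L)
  tibble::tibble(category = transition_categories(),
                 n = unname(n),
                 pct = round(100 * unname(n) / nrow(cls), 1))
}

#' Strict guideline conformance
#'
#' Percentage of patients whose (first, second) treatment pair belongs to
#' the ladder's allowed strict transitions, among patients with a second
#' treatment. Undefined (NA) when no patient has one.
#'
#' @param trajectories [build_trajectories()] output.
#' @param ladder an `rx_ladder`.
#' @return Percentage (1 decimal) or `NA`.
#' @export
guideline_conformance <- function(trajectories, ladder) {
  cls <- classify_first_transitions(trajectories, ladder)
  cls <- cls[!is.na(cls$second), ]
  if (nrow(cls) == 0) return(NA_real_)
  allowed <- vapply(ladder$strict_transitions,
                    function(p) paste(p, collapse = "\r"), "")
  got <- paste(cls$first, cls$second, sep = "\r")
  round(100 * mean(got %in% allowed), 1)
}
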