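#' Count trajectories and pool rare ones
#'
#' Trajectories occurring in at least `min_trajectory_fraction` (default
#' 0.5%) of the population are retained; rarer ones are pooled into an
#' "other" count. The population denominator is the whole cohort including
#' untreated members (switchable to treated-only via
#' `config$population_includes_untreated`). Retained + other + untreated
#' always equals cohort size.
#'
#' @param trajectories [build_trajectories()] output.
#' @param config an `rx_config`.
#' @return List: `counts` tibble (trajectory, n, fraction) sorted by
#'   decreasing n, `other_count`, `untreated_count`, `population`.
#' @export
count_trajectories <- function(trajectories, config = run_config()) {
  treated <- trajectories[trajectories$treated, ]
  untreated_count <- sum(!trajectories$treated)
  population <- if (config$population_includes_untreated) {
    nrow(trajectories)
  } else {
    nrow(treated)
  }
  if (nrow(treated) == 0) {
    return(list(counts = tibble::tibble(trajectory = character(0),
                                        n = integer(0), fraction = numeric(0)),
                other_count = 0L, untreated_count = untreated_count,
                population = population))
  }
  tab <- table(treated$trajectory)
  n <- as.integer(tab)
  keep <- n / population >= config$min_trajectory_fraction
  counts <- tibble::tibble(trajectory = names(tab)[keep], n = n[keep],
                           fraction = n[keep] / population)
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n), .data$trajectory)
  list(counts = counts,
       other_count = sum(n[!keep]),
       untreated_count = untreated_count,
       population = population)
}

#' Build the sunburst prefix tree from trajectory counts
#'
#' Ring N of a sunburst shows the N-th treatment of the retained
#' trajectories; each node's count is the number of patients whose
#' trajectory passes through that label prefix. When `config$other_wedge`
#' is set, pooled rare trajectories appear as a first-ring "other" wedge.
#'
#' @param counted [count_trajectories()] output.
#' @param config an `rx_config`.
#' @return A nested list (label, depth, patient_count, children) of class
#'   `rx_sunburst`.
#' @export
to_sunburst <- function(counted, config = run_config()) {
  seqs <- strsplit(counted$counts$trajectory, "|", fixed = TRUE)
  ns <- counted$counts$n

  grow <- function(seqs, ns, depth) {
    if (length(seqs) == 0) return(list())
    first <- vapply(seqs, `[`, "", 1)
    nodes <- list()
    for (lab in unique(first)) {
      sel <- first == lab
      kids_seqs <- lapply(seqs[sel], function(s) s[-1])
      deeper <- lengths(kids_seqs) > 0
      nodes[[length(nodes) + 1L]] <- list(
        label = lab,
        depth = depth,
        patient_count = sum(ns[sel]),
        children = grow(kids_seqs[deeper], ns[sel][deeper], depth + 1L)
      )
    }
    nodes
  }

  roots <- grow(seqs, ns, 1L)
  if (config$other_wedge && counted$other_count > 0) {
    roots[[length(roots) + 1L]] <- list(label = "other", depth = 1L,
                                        patient_count = counted$other_count,
                                        children = list())
  }
  structure(list(children = roots,
                 total = sum(ns) + counted$other_count,
                 untreated = counted$untreated_count),
            class = "rx_sunburst")
}

sunburst_depth <- function(tree) {
  walk <- function(nodes) {
    if (length(nodes) == 0) return(0L)
    max(vapply(nodes, function(n) 1L + walk(n$children), 0L))
  }
  walk(tree$children)
}

sunburst_payload <- function(tree) {
  strip <- function(nodes) {
    lapply(nodes, function(n) {
      list(label = n$label, depth = n$depth,
           patient_count = n$patient_count,
           children = strip(n$children))
    })
  }
  list(total = tree$total, untreated = tree$untreated,
       layers = sunburst_depth(tree), children = strip(tree$children))
}

# deterministic colour per class label: fixed palette over the vocabulary,
# golden-angle hues for anything beyond it
class_colour <- function(class_name) {
  base <- era_classes()
  palette <- grDevices::hcl(h = seq(15, 375, length.out = length(base) + 1)[
    seq_along(base)], c = 70, l = 60)
  i <- match(class_name, base)
  if (!is.na(i)) return(palette[i])
  if (class_name == "other") return("#bbbbbb")
  h <- (sum(utf8ToInt(class_name)) * 137.508) %% 360
  grDevices::hcl(h = h, c = 50, l = 70)
}

#' Render a sunburst tree to a self-contained HTML file
#'
#' Draws the prefix tree as nested SVG annuli: ring N holds the N-th
#' treatment, wedge angles are proportional to patient counts, mono-therapy
#' wedges take their class colour and loose combinations a striped gradient
#' of their members' colours. Colour assignment per class label is fixed, so
#' reruns produce identical files. The annotation carries the cohort size
#' and percentage treated.
#'
#' @param tree `rx_sunburst` from [to_sunburst()].
#' @param out_path output HTML path.
#' @param n_total cohort size for the annotation (optional).
#' @param pct_treated percentage treated for the annotation (optional).
#' @return Invisibly, `out_path`.
#' @export
render_sunburst <- function(tree, out_path, n_total = NULL,
                            pct_treated = NULL) {
  dir <- dirname(out_path)
  if (!dir.exists(dir)) {
    stop("render_sunburst: directory does not exist: ", dir, call. = FALSE)
  }
  cx <- 300; cy <- 300; r0 <- 55; ring <- 45
  total <- max(tree$total, 1L)
  defs <- character(0)
  paths <- character(0)

  wedge_fill <- function(label) {
    classes <- if (label == "other") "other" else label_classes(label)
    cols <- vapply(classes, class_colour, "")
    if (length(cols) == 1) return(list(fill = cols, def = NULL))
    id <- paste0("g", gsub("[^A-Za-z0-9]", "", label))
    stops <- character(0)
    k <- length(cols)
    for (i in seq_len(k)) {
      stops <- c(stops,
        sprintf('<stop offset="%.4f" stop-color="%s"/>', (i - 1) / k, cols[i]),
        sprintf('<stop offset="%.4f" stop-color="%s"/>', i / k, cols[i]))
    }
    list(fill = sprintf("url(#%s)", id),
         def = sprintf('<linearGradient id="%s">%s</linearGradient>',
                       id, paste(stops, collapse = "")))
  }

  arc_path <- function(a0, a1, r_in, r_out) {
    pt <- function(a, r) c(cx + r * cos(a), cy + r * sin(a))
    a1 <- min(a1, a0 + 2 * pi - 1e-4)
    large <- as.integer((a1 - a0) > pi)
    p1 <- pt(a0, r_in); p2 <- pt(a1, r_in)
    p3 <- pt(a1, r_out); p4 <- pt(a0, r_out)
    sprintf(paste0("M %.2f %.2f A %.2f %.2f 0 %d 1 %.2f %.2f ",
                   "L %.2f %.2f A %.2f %.2f 0 %d 0 %.2f %.2f Z"),
            p1[1], p1[2], r_in, r_in, large, p2[1], p2[2],
            p3[1], p3[2], r_out, r_out, large, p4[1], p4[2])
  }

  draw <- function(nodes, a0, span_count, depth) {
    a <- a0
    for (n in nodes) {
      frac <- n$patient_count / total
      a1 <- a + frac * 2 * pi
      f <- wedge_fill(n$label)
      if (!is.null(f$def)) defs <<- c(defs, f$def)
      r_in <- r0 + (depth - 1) * ring
      paths <<- c(paths, sprintf(
        '<path d="%s" fill="%s" stroke="white" stroke-width="1"><title>%s: %d</title></path>',
        arc_path(a - pi / 2, a1 - pi / 2, r_in, r_in + ring),
        f$fill, n$label, n$patient_count))
      draw(n$children, a, n$patient_count, depth + 1)
      a <- a1
    }
  }
  draw(tree$children, 0, total, 1)

  note <- c(
    if (!is.null(n_total)) sprintf("N = %s", format(n_total, big.mark = " ")),
    if (!is.null(pct_treated)) sprintf("%.1f%% treated", pct_treated))
  svg <- paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="600" height="640" ',
    'viewBox="0 0 600 640">',
    "<defs>", paste(unique(defs), collapse = ""), "</defs>",
    paste(paths, collapse = "\n"),
    sprintf('<text x="300" y="300" text-anchor="middle" font-size="13">%s</text>',
            paste(note, collapse = ", ")),
    "</svg>")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Treatment trajectories</title></head><body>\n",
    "<h3>Treatment trajectory sunburst</h3>\n", svg,
    "\n<script type=\"application/json\" id=\"sunburst-data\">",
    jsonlite::toJSON(sunburst_payload(tree), auto_unbox = TRUE, digits = NA),
    "</script>\n</body></html>\n")
  writeLines(html, out_path)
  invisible(out_path)
}

#' Charlson comorbidity weights
#' @param path optional YAML file; defaults to the classic weight set
#'   shipped with the package.
#' @return Named integer vector condition -> weight.
#' @export
charlson_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "charlson_weights.yaml",
                        package = "airpaths")
  }
  w <- yaml::read_yaml(path)
  vapply(w, as.integer, 0L)
}

default_comorbidities <- function() {
  c("anxiety", "atopic_disorders", "allergic_rhinitis",
    "chronic_rhinosinusitis", "depressive_disorder", "diabetes",
    "gastro_oesophageal_reflux", "nasal_polyposis", "obesity",
    "lower_respiratory_tract_infection")
}

#' Baseline characteristics table
#'
#' Cohort size, percentage male, mean age, mean Charlson Comorbidity Index
#' and per-comorbidity percentages. Comorbidity lookback is any time before
#' index, except lower respiratory tract infections which count only the
#' previous 365 days. The Charlson index sums the configured weights over
#' weight-map conditions present before index.
#'
#' @param cohort cohort tibble from [build_cohort()].
#' @param b the `rx_bundle` (person and condition lookups).
#' @param weights named weight vector, see [charlson_weights()].
#' @param comorbidities condition names to report percentages for.
#' @param charlson_conditions conditions entering the index; must all have a
#'   weight (missing weight is a hard error).
#' @return One-row tibble: n, pct_male, mean_age, mean_charlson, then one
#'   `pct_<comorbidity>` column each, 1-decimal rounding.
#' @export
baseline_table <- function(cohort, b, weights = charlson_weights(),
                           comorbidities = default_comorbidities(),
                           charlson_conditions = names(weights)) {
  missing_w <- setdiff(charlson_conditions, names(weights))
  if (length(missing_w) > 0) {
    stop("baseline_table: no Charlson weight for: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  cen <- census(cohort, b$person)
  if (nrow(cohort) == 0) {
    out <- tibble::tibble(n = 0L, pct_male = NA_real_, mean_age = NA_real_,
                          mean_charlson = NA_real_)
    for (cm in comorbidities) out[[paste0("pct_", cm)]] <- NA_real_
    return(out)
  }
  co <- b$condition_occurrence
  co <- co[co$person_id %in% cohort$person_id, ]
  idx <- stats::setNames(cohort$index_day, cohort$person_id)
  prior <- co[co$day < idx[co$person_id], ]

  pct_with <- function(cond, lookback_days = Inf) {
    hit <- prior[prior$condition == cond, ]
    if (is.finite(lookback_days)) {
      hit <- hit[hit$day >= idx[hit$person_id] - lookback_days, ]
    }
    round(100 * length(unique(hit$person_id)) / nrow(cohort), 1)
  }

  ch <- prior[prior$condition %in% charlson_conditions, ]
  ch <- unique(ch[c("person_id", "condition")])
  per_person <- tapply(weights[ch$condition], ch$person_id, sum)
  scores <- rep(0, nrow(cohort))
  scores[match(names(per_person), cohort$person_id)] <- as.numeric(per_person)

  out <- tibble::tibble(n = cen$n, pct_male = cen$pct_male,
                        mean_age = cen$mean_age,
                        mean_charlson = round(mean(scores), 1))
  for (cm in comorbidities) {
    lb <- if (cm == "lower_respiratory_tract_infection") 365 else Inf
    out[[paste0("pct_", cm)]] <- pct_with(cm, lb)
  }
  out
}

#' Distribution of first-line treatments
#'
#' Percentage of each first event label among treated members; sums to 100
#' up to rounding.
#'
#' @param trajectories [build_trajectories()] output.
#' @return Tibble (label, n, pct) sorted by decreasing n.
#' @export
first_line_distribution <- function(trajectories) {
  tr <- trajectories[trajectories$treated, ]
  if (nrow(tr) == 0) {
    return(tibble::tibble(label = character(0), n = integer(0),
                          pct = numeric(0)))
  }
  first <- vapply(tr$labels, function(l) l[1], "")
  tab <- table(first)
  out <- tibble::tibble(label = names(tab), n = as.integer(tab),
                        pct = round(100 * as.integer(tab) / nrow(tr), 1))
  dplyr::arrange(out, dplyr::desc(.data$n), .data$label)
}
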