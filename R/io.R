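#' Assemble and validate a table bundle
#'
#' A bundle is the validated in-memory form of the four OMOP-subset tables.
#' All date columns are integer day indices; validation enforces the schema
#' invariants, so downstream modules only ever see well-formed bundles.
#'
#' @param person tibble (person_id, birth_year, sex).
#' @param observation_period tibble (person_id, start_day, end_day).
#' @param condition_occurrence tibble (person_id, condition, day).
#' @param drug_exposure tibble (person_id, drug_class, start_day, end_day).
#' @return A list of the four tibbles with class `rx_bundle`.
#' @export
bundle <- function(person, observation_period, condition_occurrence,
                   drug_exposure) {
  b <- list(person = tibble::as_tibble(person),
            observation_period = tibble::as_tibble(observation_period),
            condition_occurrence = tibble::as_tibble(condition_occurrence),
            drug_exposure = tibble::as_tibble(drug_exposure))
  validate_bundle(b)
}

bundle_schemas <- function() {
  list(
    person = c("person_id", "birth_year", "sex"),
    observation_period = c("person_id", "start_day", "end_day"),
    condition_occurrence = c("person_id", "condition", "day"),
    drug_exposure = c("person_id", "drug_class", "start_day", "end_day")
  )
}

validate_bundle <- function(b) {
  schemas <- bundle_schemas()
  for (tab in names(schemas)) {
    if (is.null(b[[tab]])) {
      stop("bundle: missing table `", tab, "`", call. = FALSE)
    }
    missing <- setdiff(schemas[[tab]], names(b[[tab]]))
    if (length(missing) > 0) {
      stop("bundle: table `", tab, "` lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    b[[tab]] <- tibble::as_tibble(b[[tab]])[schemas[[tab]]]
    b[[tab]]$person_id <- as.character(b[[tab]]$person_id)
  }

  p <- b$person
  if (anyDuplicated(p$person_id)) {
    stop("person: duplicated person_id: ",
         paste(unique(p$person_id[duplicated(p$person_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(p$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    stop("person: sex must be male/female/unknown, got: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }

  op <- b$observation_period
  if (anyDuplicated(op$person_id)) {
    stop("observation_period: more than one period for person(s): ",
         paste(unique(op$person_id[duplicated(op$person_id)]),
               collapse = ", "),
         call. = FALSE)
  }
  bad <- which(op$end_day < op$start_day)
  if (length(bad) > 0) {
    stop("observation_period: end before start at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  dx <- b$drug_exposure
  bad <- which(dx$end_day < dx$start_day)
  if (length(bad) > 0) {
    stop("drug_exposure: end_day < start_day at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(dx$drug_class), drug_classes())
  if (length(unknown) > 0) {
    stop("drug_exposure: unknown drug class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  co <- b$condition_occurrence
  if (nrow(co) > 0) {
    per <- op[match(co$person_id, op$person_id), ]
    outside <- which(is.na(per$start_day) | co$day < per$start_day |
                       co$day > per$end_day)
    if (length(outside) > 0) {
      stop("condition_occurrence: day outside the person's observation ",
           "period at row(s) ", paste(outside, collapse = ", "),
           call. = FALSE)
    }
  }

  structure(b, class = "rx_bundle")
}

#' Read the four OMOP-subset tables from disk
#'
#' Accepts a directory containing `person`, `observation_period`,
#' `condition_occurrence` and `drug_exposure` as `.csv` or `.parquet`
#' (parquet requires the arrow package), or a named list/vector of file
#' paths. ISO-8601 date columns are converted to integer day indices and the
#' bundle is validated; any schema violation or unknown drug class is a hard
#' error naming the table and offending values.
#'
#' @param paths directory or named paths for the four tables.
#' @param config an `rx_config` (reserved for format options).
#' @return A validated `rx_bundle`.
#' @export
read_tables <- function(paths, config = run_config()) {
  tabs <- names(bundle_schemas())
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    files <- stats::setNames(vapply(tabs, function(t) {
      for (ext in c(".csv", ".parquet")) {
        f <- file.path(paths, paste0(t, ext))
        if (file.exists(f)) return(f)
      }
      stop("read_tables: no file for table `", t, "` in ", paths,
           call. = FALSE)
    }, character(1)), tabs)
  } else {
    missing <- setdiff(tabs, names(paths))
    if (length(missing) > 0) {
      stop("read_tables: no path given for table(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    files <- unlist(paths[tabs])
  }

  read_one <- function(f) {
    if (grepl("\\.parquet$", f, ignore.case = TRUE)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("read_tables: parquet input requires the arrow package",
             call. = FALSE)
      }
      tibble::as_tibble(arrow::read_parquet(f))
    } else {
      readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    }
  }

  raw <- lapply(files, read_one)
  names(raw) <- tabs

  to_day <- function(x, table, col) {
    if (is.numeric(x)) return(as.integer(x))
    d <- as.Date(as.character(x), format = "%Y-%m-%d")
    if (anyNA(d) && !all(is.na(x))) {
      stop("read_tables: unparseable ISO-8601 date(s) in ", table, "$", col,
           call. = FALSE)
    }
    as.integer(d)
  }
  raw$observation_period <- dplyr::rename(raw$observation_period,
    dplyr::any_of(c(start_day = "start_date", end_day = "end_date")))
  raw$condition_occurrence <- dplyr::rename(raw$condition_occurrence,
    dplyr::any_of(c(condition = "concept", day = "date")))
  raw$drug_exposure <- dplyr::rename(raw$drug_exposure,
    dplyr::any_of(c(start_day = "start_date", end_day = "end_date")))

  raw$observation_period$start_day <-
    to_day(raw$observation_period$start_day, "observation_period", "start_day")
  raw$observation_period$end_day <-
    to_day(raw$observation_period$end_day, "observation_period", "end_day")
  raw$condition_occurrence$day <-
    to_day(raw$condition_occurrence$day, "condition_occurrence", "day")
  raw$drug_exposure$start_day <-
    to_day(raw$drug_exposure$start_day, "drug_exposure", "start_day")
  raw$drug_exposure$end_day <-
    to_day(raw$drug_exposure$end_day, "drug_exposure", "end_day")

  validate_bundle(raw)
}

#' Write a bundle back to CSV files
#'
#' Inverse of [read_tables()] for the CSV path: writing then reading
#' reproduces the bundle exactly (dates serialised as ISO-8601).
#'
#' @param b an `rx_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(b, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_date_chr <- function(x) format(as.Date(x, origin = "1970-01-01"))
  out <- list(
    person = b$person,
    observation_period = dplyr::mutate(b$observation_period,
      start_date = as_date_chr(.data$start_day),
      end_date = as_date_chr(.data$end_day),
      .keep = "unused"),
    condition_occurrence = dplyr::mutate(b$condition_occurrence,
      concept = .data$condition, date = as_date_chr(.data$day),
      .keep = "unused"),
    drug_exposure = dplyr::mutate(b$drug_exposure,
      start_date = as_date_chr(.data$start_day),
      end_date = as_date_chr(.data$end_day),
      .keep = "unused")
  )
  paths <- character(0)
  for (tab in names(out)) {
    f <- file.path(dir, paste0(tab, ".csv"))
    readr::write_csv(out[[tab]], f, progress = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Write pipeline results and a checksum manifest
#'
#' Serialises the tables produced by [run_pipeline()] — trajectory counts,
#' the seven-row transition table, baseline characteristics, first-line
#' distribution, cohort and attrition — plus the sunburst JSON and HTML, and
#' returns a manifest of files with MD5 checksums. Empty results yield
#' header-only CSVs, and a rerun on identical results is byte-identical.
#'
#' @param results list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Tibble manifest (file, md5).
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("write_outputs: cannot create directory ", out_dir, call. = FALSE)
  }
  tables <- list(
    trajectory_counts = results$trajectory_counts,
    transition_table = results$transition_table,
    baseline = results$baseline,
    first_line = results$first_line,
    cohort = results$cohort,
    attrition = results$attrition,
    drug_eras = results$eras,
    events = results$events,
    trajectories = results$trajectory_table
  )
  files <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], f, progress = FALSE)
    files <- c(files, f)
  }
  if (!is.null(results$sunburst)) {
    fj <- file.path(out_dir, "sunburst.json")
    jsonlite::write_json(sunburst_payload(results$sunburst), fj,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fh <- file.path(out_dir, "sunburst.html")
    render_sunburst(results$sunburst, fh,
                    n_total = results$n_cohort,
                    pct_treated = results$percent_treated)
    files <- c(files, fj, fh)
  }
  tibble::tibble(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
}
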