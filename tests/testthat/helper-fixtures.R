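# Hand-built fixtures with hand-computed expectations.

D <- function(x) as.integer(as.Date(x))

# Twelve persons covering every exclusion reason for the asthma cohort.
# Expected (default config):
#   asthma diagnosed 11; excluded: window 2 (P03 too early, P04 too late),
#   age 2 (P05; P09 also has short prior obs but age takes precedence),
#   prior obs 1 (P06), follow-up 1 (P07), prior COPD 1 (P08);
#   included 4: P01, P02, P11 (index = earlier of two records), P12 (COPD
#   only after index does not exclude).
#   COPD cohort: P08 included, P12 excluded (follow-up); disjoint cohorts.
twelve_person_bundle <- function() {
  person <- tibble::tibble(
    person_id = sprintf("P%02d", 1:12),
    birth_year = c(1980L, 1975L, 1980L, 1980L, 2000L, 1970L, 1970L, 1960L,
                   2005L, 1990L, 1950L, 1985L),
    sex = c("female", "female", "male", "male", "male", "female", "male",
            "male", "female", "female", "male", "male")
  )
  op <- tibble::tibble(
    person_id = person$person_id,
    start_day = D(c("2010-01-01", "2013-01-01", "2008-01-01", "2018-01-01",
                    "2012-01-01", "2011-06-01", "2014-01-01", "2011-01-01",
                    "2015-10-01", "2010-01-01", "2010-01-01", "2010-06-01")),
    end_day = D(c("2016-06-30", "2018-12-31", "2014-01-01", "2024-01-01",
                  "2019-01-01", "2016-01-01", "2017-06-30", "2018-06-01",
                  "2019-12-31", "2019-12-31", "2017-12-31", "2016-06-01"))
  )
  co <- tibble::tibble(
    person_id = c("P01", "P02", "P03", "P04", "P05", "P06", "P07", "P08",
                  "P08", "P09", "P10", "P11", "P11", "P12", "P12"),
    condition = c("asthma", "asthma", "asthma", "asthma", "asthma", "asthma",
                  "asthma", "asthma", "copd", "asthma", "anxiety", "asthma",
                  "asthma", "asthma", "copd"),
    day = D(c("2012-06-01", "2015-03-10", "2009-12-31", "2020-06-01",
              "2015-01-01", "2012-01-01", "2016-01-01", "2014-01-01",
              "2013-06-01", "2016-01-01", "2011-01-01", "2013-05-01",
              "2014-01-01", "2012-03-01", "2015-01-01"))
  )
  dx <- tibble::tibble(person_id = character(0), drug_class = character(0),
                       start_day = integer(0), end_day = integer(0))
  bundle(person, op, co, dx)
}

expected_asthma_attrition <- function() {
  tibble::tibble(
    reason = c("diagnosed", "not_in_index_window", "below_min_age",
               "insufficient_prior_observation", "insufficient_followup",
               "prior_other_disease", "included"),
    n = c(11L, 2L, 2L, 1L, 1L, 1L, 4L)
  )
}

# wide calendar window so small-day toy examples are judged on the other rules
wide_config <- function(...) {
  run_config(index_window = c(0L, 10000000L), ...)
}

# a tiny ladder object for conformance tests with hand-chosen allowed pairs
manual_ladder <- function(allowed) {
  structure(list(disease = "asthma",
                 levels = c(SABA = 1L, ICS = 2L, LTRA = 2L,
                            `LABA-ICS` = 3L),
                 level_rules = c(biologics = 5L, steroid_maintenance = 5L),
                 rescue_classes = c("SABA", "SAMA", "SABA-SAMA"),
                 strict_transitions = allowed),
            class = "rx_ladder")
}

# trajectories tibble straight from label sequences
traj_table <- function(label_seqs, n_untreated = 0L) {
  rows <- lapply(seq_along(label_seqs), function(i) {
    tibble::tibble(person_id = sprintf("T%04d", i), treated = TRUE,
                   trajectory = paste(label_seqs[[i]], collapse = "|"),
                   labels = list(label_seqs[[i]]))
  })
  if (n_untreated > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      person_id = sprintf("U%04d", seq_len(n_untreated)), treated = FALSE,
      trajectory = "", labels = lapply(seq_len(n_untreated),
                                       function(i) character(0)))
  }
  dplyr::bind_rows(rows)
}
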