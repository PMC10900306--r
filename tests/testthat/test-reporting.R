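test_that("the 0.5% retention threshold is inclusive and conserves counts", {
  cfg <- run_config()
  # 1000 patients: one trajectory at exactly 0.5% retained, one below pooled
  seqs <- c(rep(list(c("SABA")), 991), rep(list(c("ICS")), 5),
            rep(list(c("LTRA")), 4))
  counted <- count_trajectories(traj_table(seqs), cfg)
  expect_true("ICS" %in% counted$counts$trajectory)
  expect_false("LTRA" %in% counted$counts$trajectory)
  expect_equal(counted$other_count, 4L)
  expect_equal(sum(counted$counts$n) + counted$other_count +
                 counted$untreated_count, 1000L)

  # all patients share one trajectory
  one <- count_trajectories(traj_table(rep(list(c("SABA")), 50)), cfg)
  expect_equal(nrow(one$counts), 1L)
  expect_equal(one$other_count, 0L)
})

test_that("the sunburst tree carries brute-force prefix counts", {
  cfg <- run_config()
  counted <- count_trajectories(
    traj_table(c(rep(list(c("SABA")), 10), rep(list(c("SABA", "ICS")), 5))),
    cfg)
  tree <- to_sunburst(counted, cfg)
  root <- tree$children[[1]]
  expect_equal(root$label, "SABA")
  expect_equal(root$patient_count, 15L)
  expect_equal(root$children[[1]]$label, "ICS")
  expect_equal(root$children[[1]]$patient_count, 5L)

  empty <- to_sunburst(count_trajectories(traj_table(list(), 3L), cfg), cfg)
  expect_length(empty$children, 0L)
})

test_that("sunburst prefix counts equal the brute-force oracle on random
           multisets", {
  labs <- c("SABA", "ICS", "LTRA", "LABA-ICS")
  cfg <- run_config(min_trajectory_fraction = 1e-6)  # retain everything
  withr::with_seed(55, {
    for (rep in 1:5) {
      n <- sample(50:200, 1)
      seqs <- lapply(seq_len(n), function(i) {
        k <- sample(1:5, 1)
        s <- sample(labs, k, replace = TRUE)
        rle(s)$values
      })
      counted <- count_trajectories(traj_table(seqs), cfg)
      got <- sunburst_prefix_counts(to_sunburst(counted, cfg))
      want <- oracle_prefix_counts(seqs)
      expect_setequal(names(got), names(want))
      for (k in names(want)) expect_equal(got[[k]], want[[k]], info = k)
    }
  })
})

test_that("render_sunburst writes a deterministic self-contained HTML", {
  cfg <- run_config()
  counted <- count_trajectories(
    traj_table(c(rep(list(c("SABA")), 10), rep(list(c("SABA", "ICS")), 5))),
    cfg)
  tree <- to_sunburst(counted, cfg)
  f1 <- withr::local_tempfile(fileext = ".html")
  f2 <- withr::local_tempfile(fileext = ".html")
  render_sunburst(tree, f1, n_total = 15, pct_treated = 100)
  render_sunburst(tree, f2, n_total = 15, pct_treated = 100)
  h <- readLines(f1)
  expect_true(any(grepl("SABA", h)))
  expect_true(any(grepl("ICS", h)))
  expect_identical(readLines(f2), h)
  expect_error(render_sunburst(tree, file.path(tempdir(), "no/such/dir/x.html")),
               "directory")
})

test_that("a five-layer cohort yields five layers in the JSON payload", {
  cfg <- run_config(min_trajectory_fraction = 1e-6)
  seqs <- rep(list(c("SABA", "ICS", "LABA-ICS", "LTRA", "LABA-LAMA-ICS")), 20)
  tree <- to_sunburst(count_trajectories(traj_table(seqs), cfg), cfg)
  payload <- jsonlite::fromJSON(jsonlite::toJSON(
    airpaths:::sunburst_payload(tree), auto_unbox = TRUE), simplifyVector = FALSE)
  expect_equal(payload$layers, 5L)
})

test_that("baseline table recounts comorbidities and Charlson weights", {
  b <- bundle(
    person = tibble::tibble(person_id = c("A", "B"),
                            birth_year = c(1970L, 1980L),
                            sex = c("male", "female")),
    observation_period = tibble::tibble(person_id = c("A", "B"),
                                        start_day = c(0L, 0L),
                                        end_day = c(3000L, 3000L)),
    condition_occurrence = tibble::tibble(
      person_id = c("A", "A", "A", "A", "B"),
      condition = c("asthma", "anxiety", "diabetes",
                    "congestive_heart_failure", "asthma"),
      day = c(1000L, 500L, 600L, 700L, 1000L)),
    drug_exposure = tibble::tibble(person_id = character(0),
                                   drug_class = character(0),
                                   start_day = integer(0),
                                   end_day = integer(0))
  )
  cohort <- tibble::tibble(person_id = c("A", "B"), disease = "asthma",
                           index_day = c(1000L, 1000L),
                           followup_end_day = c(3000L, 3000L),
                           age_at_index = c(32L, 22L))
  tab <- baseline_table(cohort, b)
  expect_equal(tab$pct_anxiety, 50.0)
  expect_equal(tab$mean_charlson, 1.0)  # A: diabetes 1 + CHF 1 = 2; B: 0
  expect_error(baseline_table(cohort, b, charlson_conditions = "gout"),
               "no Charlson weight")

  # lower respiratory tract infections look back one year only
  b2 <- bundle(b$person, b$observation_period,
               dplyr::bind_rows(b$condition_occurrence,
                 tibble::tibble(person_id = c("A", "B"),
                                condition = "lower_respiratory_tract_infection",
                                day = c(200L, 900L))),
               b$drug_exposure)
  tab2 <- baseline_table(cohort, b2)
  expect_equal(tab2$pct_lower_respiratory_tract_infection, 50.0)
})

test_that("first-line distribution covers treated patients and sums to
           100", {
  tr <- traj_table(list(c("SABA"), c("SABA", "ICS"), c("ICS"), c("LTRA")))
  fl <- first_line_distribution(tr)
  expect_equal(fl$pct[fl$label == "SABA"], 50.0)
  expect_equal(fl$pct[fl$label == "ICS"], 25.0)
  expect_lt(abs(sum(fl$pct) - 100), 0.2)
  one <- first_line_distribution(traj_table(list(c("LTRA", "ICS"))))
  expect_equal(one$pct, 100.0)
})
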