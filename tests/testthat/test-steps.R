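test_that("transition classification follows the stated precedence", {
  lad <- default_ladder("asthma")
  expect_equal(classify_transition("SABA", NA, lad), "no_followup")
  expect_equal(classify_transition("SABA", "steroid_burst", lad),
               "exacerbation_start")
  expect_equal(classify_transition("steroid_burst", "SABA", lad),
               "exacerbation_end")
  expect_equal(classify_transition("SABA", "LABA-ICS", lad), "step_up")
  expect_equal(classify_transition("LABA-ICS", "SABA", lad), "step_down")
  expect_equal(classify_transition("ICS", "LTRA", lad), "switching")
  # unclassifiable labels fall into "other"
  expect_equal(classify_transition("xanthines", "SABA", lad), "other")
  # bursts are transparent when both sides carry one
  expect_equal(classify_transition("SABA+steroid_burst",
                                   "LABA-ICS+steroid_burst", lad),
               "step_up")
  # rescue members don't change the level of a controller set
  expect_equal(classify_transition("ICS+SABA", "LABA-ICS", lad), "step_up")
  # rule-based top level: biologics and maintenance steroids
  expect_equal(classify_transition("LABA-ICS", "biologics+LABA-ICS", lad),
               "step_up")
  expect_equal(classify_transition("steroid_maintenance", "ICS", lad),
               "step_down")
})

test_that("step-up and step-down are antisymmetric across the ladder", {
  for (disease in c("asthma", "copd")) {
    lad <- default_ladder(disease)
    labs <- names(lad$levels)
    for (a in labs) {
      for (b in labs) {
        if (a == b) next
        ab <- classify_transition(a, b, lad)
        ba <- classify_transition(b, a, lad)
        expect_equal(ab == "step_up", ba == "step_down",
                     info = paste(disease, a, "->", b))
      }
    }
  }
})

test_that("the transition table partitions treated patients and sums to
           100", {
  lad <- default_ladder("asthma")
  tr <- traj_table(list(c("SABA"), c("SABA"),
                        c("SABA", "LABA-ICS"),
                        c("LABA-ICS", "ICS")),
                   n_untreated = 3L)
  tab <- transition_table(tr, lad)
  expect_equal(tab$category, transition_categories())
  expect_equal(tab$pct[tab$category == "no_followup"], 50.0)
  expect_equal(tab$pct[tab$category == "step_up"], 25.0)
  expect_equal(tab$pct[tab$category == "step_down"], 25.0)
  expect_equal(sum(tab$n), 4L)  # untreated excluded from the denominator
  expect_lt(abs(sum(tab$pct) - 100), 0.2)

  all_mono <- traj_table(list("SABA", "ICS", "LTRA"))
  tab <- transition_table(all_mono, lad)
  expect_equal(tab$pct[tab$category == "no_followup"], 100.0)

  expect_equal(nrow(transition_table(traj_table(list(), 4L), lad)), 0L)
})

test_that("classification partitions random trajectories exactly once", {
  lad <- default_ladder("asthma")
  labs <- c("SABA", "ICS", "LTRA", "LABA-ICS", "steroid_burst", "xanthines")
  withr::with_seed(77, {
    seqs <- lapply(1:60, function(i) {
      n <- sample(1:3, 1)
      s <- sample(labs, n)
      s[!duplicated(s)]
    })
  })
  tr <- traj_table(seqs)
  cls <- classify_first_transitions(tr, lad)
  expect_equal(nrow(cls), length(seqs))
  expect_true(all(cls$category %in% transition_categories()))
  tab <- transition_table(tr, lad)
  expect_lt(abs(sum(tab$pct) - 100), 0.2)
})

test_that("guideline conformance counts allowed pairs among patients with a
           second treatment", {
  tr <- traj_table(list(c("SABA", "ICS"), c("SABA", "LTRA")))
  expect_equal(guideline_conformance(tr, manual_ladder(list(c("SABA",
                                                              "ICS")))),
               50.0)
  expect_equal(guideline_conformance(tr, manual_ladder(list())), 0.0)
  all_pairs <- list(c("SABA", "ICS"), c("SABA", "LTRA"))
  expect_equal(guideline_conformance(tr, manual_ladder(all_pairs)), 100.0)
  # patients without a second treatment never move the value
  tr2 <- dplyr::bind_rows(tr, traj_table(list("SABA"))[1, ])
  expect_equal(guideline_conformance(tr2, manual_ladder(list(c("SABA",
                                                               "ICS")))),
               50.0)
  only_mono <- traj_table(list("SABA"))
  expect_true(is.na(guideline_conformance(only_mono, manual_ladder(list()))))
})

test_that("ladder levels resolve rescue sets and rule classes", {
  lad <- default_ladder("asthma")
  expect_equal(ladder_level("SABA", lad), 1L)
  expect_equal(ladder_level("SABA+SAMA", lad), 1L)      # rescue-only set
  expect_equal(ladder_level("ICS+LABA", lad), 3L)       # explicit map entry
  expect_equal(ladder_level("ICS+SABA", lad), 2L)       # rescue dropped
  expect_equal(ladder_level("LTRA+SABA", lad), 2L)      # rescue dropped
  expect_equal(ladder_level("biologics+ICS", lad), 5L)  # rule class
  expect_true(is.na(ladder_level("xanthines", lad)))
  expect_error(default_ladder("asthma", path = "nope.yaml"), "no ladder")
})
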