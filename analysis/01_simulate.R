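#!/usr/bin/env Rscript
# Stage 1: simulate two source populations with planted ground truth.
#
# Asthma: EHR-style prescription records, a six-trajectory mix, 20%
# untreated, and deliberately ineligible persons of every kind.
# COPD: claims-style dispensing records (30-day fills, ~10-day refill gaps)
# and a COPD-flavoured trajectory mix.
# Writes the four OMOP-subset tables plus ground_truth.csv per disease.

library(airpaths)

out_root <- "results/data"
cfg <- run_config()

asthma_sc <- scenario_config(
  n_persons = 2000, disease = "asthma", untreated_fraction = 0.2,
  trajectory_distribution = default_trajectories(),
  exposure_style = "prescription",
  ineligible_fractions = c(too_young = 0.05, short_prior_obs = 0.05,
                           short_followup = 0.05, prior_other_disease = 0.05),
  comorbidity_prevalences = c(anxiety = 0.2, allergic_rhinitis = 0.25,
                              diabetes = 0.1, obesity = 0.12,
                              lower_respiratory_tract_infection = 0.2),
  seed = 101)

copd_sc <- scenario_config(
  n_persons = 1000, disease = "copd", untreated_fraction = 0.3,
  trajectory_distribution = list(
    list(sequence = list("SAMA"), prob = 0.20),
    list(sequence = list("LAMA"), prob = 0.20),
    list(sequence = list("LAMA", "LABA-LAMA"), prob = 0.20),
    list(sequence = list("SABA", "LABA"), prob = 0.15),
    list(sequence = list("steroid_burst", "LAMA"), prob = 0.15),
    list(sequence = list("LAMA", "LABA-LAMA", "LABA-LAMA-ICS"), prob = 0.10)),
  exposure_style = "dispensing",
  ineligible_fractions = c(too_young = 0.05, short_prior_obs = 0.05,
                           short_followup = 0.05, prior_other_disease = 0.05),
  comorbidity_prevalences = c(diabetes = 0.2, congestive_heart_failure = 0.1,
                              depressive_disorder = 0.15,
                              lower_respiratory_tract_infection = 0.3),
  seed = 202)

for (sc in list(asthma = asthma_sc, copd = copd_sc)) {
  g <- generate_scenario(sc, cfg)
  dir <- file.path(out_root, sc$disease)
  write_tables(g$bundle, dir)
  readr::write_csv(g$ground_truth, file.path(dir, "ground_truth.csv"))
  cat(sprintf(
    "%s: %d persons (%d eligible, %d treated), %d exposure records -> %s\n",
    sc$disease, sc$n_persons, sum(g$ground_truth$eligible),
    sum(g$ground_truth$treated), nrow(g$bundle$drug_exposure), dir))
}
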