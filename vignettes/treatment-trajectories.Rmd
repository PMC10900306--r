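---
title: "Modelling treatment trajectories in newly diagnosed asthma and COPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling treatment trajectories in newly diagnosed asthma and COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airpaths)
```

## The problem

Observational health databases record respiratory prescriptions or
dispensings as scattered, overlapping intervals. To say anything about how
newly diagnosed asthma or COPD patients are actually treated — what they
start on, whether therapy is stepped up or down, how often an acute
exacerbation interrupts maintenance treatment — those raw records must be
turned into an interpretable per-patient object: the *treatment trajectory*,
the ordered sequence of drug-class regimens a patient traverses after
diagnosis. `airpaths` implements that derivation as a pipeline of small,
separately testable stages, and ships a synthetic-data generator that plants
known trajectories so every stage can be validated against ground truth.

## Cohort construction

Two mutually exclusive new-diagnosis cohorts are built from OMOP-shaped
tables. Cohort entry (the *index date*) is the first recorded diagnosis.
Membership requires:

* index date in the configured calendar window (2010-01-01 to 2019-12-31);
* age at index of at least 18 (asthma) or 40 (COPD) years;
* at least 365 days of observation before index (so the diagnosis is
  plausibly new) and at least 1095 days after it (so there is room to
  observe a trajectory);
* no diagnosis of the other disease on or before index.

Time is integer day indices; intervals are closed and
`duration = end − start + 1`, which makes every "< 30 days" / "≥ 30 days"
rule unambiguous and lets brute-force day-level oracles verify the interval
arithmetic. "One year" is fixed at 365 days and "three years" at 1095; age
is index year minus birth year, since only year granularity is available.
Each person has a single observation period — re-enrollment is out of scope
and sources with multiple periods must pre-merge them.

A cross-diagnosis *after* index does not expel a patient: the cohorts are
defined at entry, and post-index overlap is a separate question this package
does not address. Exclusion reasons are tallied with a fixed precedence
(calendar window, age, prior observation, follow-up, other-disease history)
so attrition tables are deterministic; a person failing several rules is
counted once, under the first.

## Drug eras

Within one person and drug class, exposure records separated by at most 30
uncovered days are merged into a *drug era*; eras shorter than 5 days are
discarded. Two choices deserve note:

* the gap between `[a1, b1]` and `[a2, b2]` is `a2 − b1 − 1`, the count of
  fully uncovered days, and merging applies when that count is ≤ 30 — "a
  maximum gap of 30 days" read as "up to 30 uncovered days tolerated";
* the 5-day minimum applies *after* merging, so chains of short dispensings
  survive as one era — it is eras that are dropped, not records.

Only treatment from the index day onward is analysed. An exposure straddling
index keeps its post-index portion by default (`truncate_at_index`); setting
the switch to `FALSE` keeps straddling records whole, since the convention
for records that begin before diagnosis is genuinely open.

Systemic glucocorticoid eras are then split by duration: under 30 days is a
`steroid_burst` — the marker of an acute exacerbation — and 30 days or more
is `steroid_maintenance`. The merged era's duration decides, not any single
record's.

## Overlap resolution into treatment events

Eras of different classes overlap freely; trajectories need a single
timeline of regimens. Resolution is iterative and pairwise: repeatedly take
the overlapping pair whose overlap starts earliest and apply

* **combination** — overlap ≥ 30 days, or exactly the full duration of one
  of the two events: the overlap becomes an event carrying the union of the
  class sets, and the non-overlapping remnants remain as events;
* **switch** — any shorter overlap: the earlier event is truncated the day
  before the later one starts (the later class wins the contested window).

Ties in overlap start are broken by longer event first, then alphabetical
label, making the procedure deterministic under any input order. A
combination event re-enters the pool, so triple and higher combinations
emerge from repeated pairwise steps. Each step strictly reduces total
pairwise overlap (or the event count), so the procedure terminates; a guard
caps iterations defensively.

Two open points were settled as package design choices. First, the "full
duration" clause is judged on the *current* (possibly already split)
intervals, not the original eras — the remnant is what the patient is
actually holding when the overlap occurs (`full_duration_on_remnant`
switches this). Second, remnants shorter than 5 days created by splitting
are dropped, reusing the era minimum symmetrically
(`drop_short_remnants`). Both are configuration switches so either reading
can be run.

After resolution, consecutive events with identical class sets are merged,
labels are rendered canonically (alphabetical `+`-join; fixed-combination
inhalers such as `LABA-ICS` stay atomic and distinct from the loose
combination `ICS+LABA`), and the per-patient sequence is truncated at 5
layers — deeper rings are unreadable in a sunburst and vanishingly rare;
`max_trajectory_depth` raises the cap.

## Transition classification

Only the first transition after first-line treatment feeds the seven-row
reporting table. Classification precedence:

1. no second event → *no follow-up treatment*;
2. a steroid burst present in the second event but not the first → *start
   of acute exacerbation*; the reverse → *end of acute exacerbation*;
3. otherwise ladder levels decide *step-up* / *step-down*; equal levels
   with different labels are *switching*; any unclassifiable label →
   *other*.

When **both** events contain a burst the burst is treated as transparent and
the non-burst members are compared; if stripping leaves nothing to compare
the transition is *other*. This both-burst convention is a package decision
— the source guidance does not cover it.

The intensity ladders are data, not code: YAML files under `inst/extdata`
reconstructed from the GINA and GOLD step structures (rescue-only regimens
at level 1 up to biologics / maintenance steroids at level 5 for asthma;
short-acting bronchodilators up to triple therapy plus PDE4/xanthines for
COPD). A label missing from the explicit map falls back to rules: classes
like biologics force their level; rescue classes are dropped and the
remainder looked up (so `ICS+SABA` sits at the ICS level); rescue-only sets
are level 1. Strict-definition conformance uses an editable allowed-pair
list in the same files. **Conformance numbers are only meaningful after the
ladder and allowed set have been reviewed for the question at hand**, and
are not comparable to values computed under other ladder definitions.

## Aggregation and reporting

Trajectories occurring in at least 0.5% of the population are retained;
rarer ones are pooled into an explicit "other" wedge (`other_wedge`
disables it). The denominator includes untreated patients
(`population_includes_untreated` switches to treated-only). The retained
multiset becomes a prefix tree whose node counts are patients passing
through each label prefix; the HTML sunburst is a direct SVG rendering of
that tree with a fixed colour per class (combination wedges show striped
member colours), so reruns are byte-identical.

Baseline tables report size, percentage male (unknown sex excluded from the
denominator), mean age, per-comorbidity percentages (any time before index;
lower respiratory tract infections restricted to the previous 365 days) and
the mean Charlson Comorbidity Index using the classic weight set shipped as
editable YAML — a missing weight for a configured category is a hard error
rather than a silent zero.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a realism
exercise. It emulates the two exposure-recording styles seen across source
databases: *prescription* style (one record spanning a whole treatment
period, as in EHR systems) and *dispensing* style (≈30-day fills with
stochastic refill gaps, as in claims systems). Its guarantee is that planted
structure is recoverable by construction: gaps between distinct planted
events always exceed the 30-day era gap, refill gaps within an event never
do, and multi-class events are planted as fully overlapping intervals, which
the full-duration clause classifies as combinations regardless of length.
Scenarios violating these constraints (event durations below the era
minimum, inter-event gaps within the merge range, consecutive identical
class sets) are rejected before generation.

Defaults, chosen once as the simulated study conditions: treatment events
last 120 ± 30 days (clamped to [30, 365]) — a typical maintenance stretch;
inter-event gaps are 90 ± 30 days (clamped above 30) — a clear treatment
break; dispensing fills cover 30 days with refill gaps of 10 ± 5 days
(clamped to [0, 30]); 20% of eligible persons stay untreated; first
exposure falls 0–60 days after index; steroid-burst events are planted at
5–29 days and maintenance at 30–90 days, matching the classification
boundaries they must land in. Ineligible persons are generated one reason
apiece (too young, short prior observation, short follow-up, prior
other-disease diagnosis) so attrition is checkable exactly; comorbidities
are sampled independently per condition since only marginal prevalences are
meaningful here.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: irregular refill behaviour beyond a clamped
Gaussian gap (no early refills, stockpiling or abandonment), dose or device
changes within a class, correlated comorbidity, seasonality, mortality or
informative censoring beyond the observation-period end, and ambiguous
overlap patterns (planted events are deliberately unambiguous; the
resolution rules' behaviour on messier real overlaps is exercised by the
randomized property tests instead).

## Numerical and testing choices

Everything is integer day arithmetic; no floating-point tolerance enters
the pipeline itself. Percentages are reported at one decimal. Determinism
is part of the contract: a seed plus a scenario reproduces tables exactly,
and the pipeline's structural invariants (cohort disjointness, retained +
pooled + untreated = cohort size, transition percentages summing to 100
within rounding) are asserted on every run rather than only in tests.

The test suite validates era construction against a day-set bitmap oracle
on 1000 randomized exposure sets, overlap resolution against hand-traced
rule examples and a day-level labelling oracle, cohort filtering against a
12-person hand-computed fixture, and recovery of planted trajectories
(2000 prescription-style patients), event counts (500 dispensing-style
patients) and transition mixes (1000 patients) at three binomial standard
errors. The analysis scripts run the same machinery at 2000 (asthma) and
1000 (COPD) persons — sizes at which binomial error on a 0.5%-threshold
quantity is already small — and finish in well under a minute per stage.

## Known limitations

* The overlap-resolution procedure is a faithful reconstruction of two
  published rules plus declared tie-breaks; the original authors' exact
  iterative algorithm lives in earlier work and its supplement, and other
  reconstructions could order contested pairs differently.
* Guideline ladders and strict transition sets are reconstructions; the
  package makes conformance a function of editable data for exactly that
  reason.
* No dose information: step distinctions that hinge on low/medium/high ICS
  cannot be expressed.
* Trajectories ignore time between events and event durations by design —
  the sunburst shows sequence, not tempo.
* Single observation period per person; no re-enrollment handling.
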