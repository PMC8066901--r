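---
title: "Humane-endpoint scoring for chemically induced colorectal carcinogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Humane-endpoint scoring for chemically induced colorectal carcinogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hescore)
```

## The monitoring problem

Rat models of colorectal carcinogenesis induced with 1,2-dimethylhydrazine
(DMH) are classified as severe: a fraction of induced animals dies
prematurely of hemorrhagic enteritis rather than of the tumours the model is
built to study. Humane-endpoint (HE) monitoring aims to catch those animals
before death, on welfare grounds and because unplanned deaths truncate the
experiment. `hescore` implements the complete monitoring pipeline for this
design: an ordinal welfare score sheet with euthanasia rules, body-metric
computations, an early-warning detector for the stereotyped pre-death sign
sequence, survival and group statistics, and a seeded simulator that
generates cohorts with the same longitudinal structure so that every stage
of the pipeline can run, and be tested, without any animal data.

The reference design the defaults encode is: 29 male Wistar rats in four
arms — two vehicle control arms (`CTRL1`, `CTRL2`, n = 6 each) and two
induced arms (`CRC1` n = 8, `CRC2` n = 9) — with seven weekly
intraperitoneal administrations (weeks 1–7 on the study clock), and
scheduled sacrifices of arms 1 at week 11 and arms 2 at week 17 after the
first administration.

## The score sheet and the decision rule

The default rubric (`sheet_table1()`) has 14 ordinal parameters in three
categories (general appearance and consciousness, behaviour, clinical
signs), each scored on a subset of {0, 1, 2, 3}; "---" cells of the
published rubric are *unavailable* levels, not zeros, so e.g. Posture admits
only {0, 1}. The maximum attainable total is 36. Two rules mandate removal
and euthanasia:

* **Critical limit**: a total HE score of 4 or more. The total is the plain
  sum of the per-parameter scores of a complete weekly record.
* **Single-parameter triggers**: body-weight loss above 20%, stupor/coma,
  necrosis of induced skin lesions, or inflammatory exudate in them — each
  mandates euthanasia regardless of the total.

```{r}
sheet <- sheet_table1()
summary(sheet)
```

Three observers score independently; `merge_observers()` combines them by
the per-parameter **maximum**. The published protocol states the
observations were independent and cross-checked but does not give a
consensus rule; the maximum is the welfare-conservative choice (an animal is
never under-scored because one observer missed a sign), and it is idempotent
and order-invariant, which the tests verify as properties.

Incomplete weekly records get `total = NA` and are excluded from group
means, but single-parameter triggers still fire on whatever was observed:
the alternative (dropping partial records entirely) could silently ignore a
comatose animal because a different parameter went unrecorded.

The refined rubric (`sheet_refined()`) extends the sheet with the three
signs that preceded the observed deaths: abdominal-temperature elevation
(scored 0/1/2 at 1 and 2 SDs above the concurrent control mean), priapism
(0 absent / 2 present), and sudden weekly body-weight gain (0 below 6%,
1 for 6–10%, 2 above 10%). The published appendix naming these additions
does not print the level wording, so these levels are this package's
declared reconstruction — they ship in `inst/extdata/refined.json` precisely
so that they are explicit and editable rather than implied. Whether the
critical limit should change for a 17-parameter sheet is not established;
we keep it at 4, which is conservative (more parameters can only reach the
limit sooner).

## Body metrics

Ponderal gain is computed against the **final** weight,

$$PG(\%) = \frac{w_{final} - w_{initial}}{w_{final}} \times 100,$$

so it is signed, bounded above by 100, and a loss between the same two
weights has a different magnitude than the gain (the denominator moves).
`weekly_ponderal_series()` applies the formula over consecutive weighings;
reconstructing weights from a gain series inverts it exactly
(to 1e-9 relative error in the tests).

Terminal body weights in this model are corrected by subtracting the full
intestine and its content (`corrected_body_weight()`): impaction and
distension of the cecum in induced animals otherwise masquerade as body
mass. Food and water consumption is the repository-weight difference per
cage divided by animal-days (`mean_consumption()`); refills must be
recorded as separate periods, which the validation enforces.

## The prodrome detector

Animals that died prematurely showed a uniform sequence: a sudden weekly
weight gain of roughly 6–10%, then a swollen abdomen, diarrhea, priapism,
and death, spread over several weeks. `detect_prodrome()` turns weights and
signs into weekly alert levels:

* `watch` — weekly gain at or above 6%, or any single sign;
* `high` — weekly gain above 10%, or a sudden gain together with any later
  sign, or two or more distinct signs.

Thresholds are arguments (`watch_pg`, `high_pg`), defaulting to the 6% and
10% magnitudes of the observed cases. Alerts are cumulative over an
animal's history, so they never de-escalate, and adding a sign can only
raise the level (a tested monotonicity property).

A known limitation is that the thresholds are memoryless: young rats grow
fast, and in the first two weeks of the protocol normal juvenile growth
(around 9% per week, occasionally above 10%) legitimately crosses them.
The observed first-administration-week gains of the animals that later died
were 7.6–10.9% — indistinguishable from normal growth at that age. The
detector is therefore informative from mid-protocol onward, once growth has
slowed to a few percent per week; a growth-adjusted baseline would be the
natural refinement but is deliberately out of scope of the fixed-threshold
rule implemented here.

## Survival statistics

Scheduled sacrifice is **administrative right-censoring**; spontaneous
death is the event. Humane euthanasia is an optional event type: the
default event set for reproducing the survival rates is spontaneous deaths
only (none of the monitored animals reached the critical limit, so the
published rates contain no euthanasia events), but counting euthanasia as a
welfare failure is one argument away (`events =`). On the reconstructed
roster this gives:

```{r}
ev <- reconstruction_events()
summary_rates <- sapply(split(ev, ev$arm), survival_rate)
round(summary_rates, 1)
logrank_test(ev[ev$arm == "CRC1", ], ev[ev$arm == "CRC2", ])
```

The Kaplan–Meier estimator and the log-rank test are delegated to the
`survival` package behind `km_estimate()` and `logrank_test()`; the test
suite checks both against independent oracles (explicit risk-set products,
and the textbook O−E/V log-rank sums). A reconstruction note: the published
sacrifice section swaps the induced-arm sizes relative to what the survival
rates imply; enrolments of 8 (CRC1) and 9 (CRC2) are the only ones
consistent with 2 deaths → 75.0% and 3 deaths → 66.7% and 17 induced
animals in total, so the roster uses those.

Group HE scores use the group-mean formula (sum of the animals' totals over
the number of animals); the pipeline summarises each animal by its mean
weekly total first, so animals observed for different numbers of weeks
weigh equally. `compare_groups()` wraps one-way ANOVA (Tukey HSD or
Bonferroni post hoc) and the arm-by-timepoint two-way layout with type-II
sums of squares — the original analysis does not state its SS type, and
type II is the conventional choice for a balanced-ish factorial without
ordered testing of main effects.

## The cohort simulator

`simulate_cohort()` generates the full dataset (weights, score
observations, signs, thermography, cage consumption, terminal events) with
one root seed; every animal draws from a substream keyed on its id, so
enlarging an arm does not perturb existing animals. Defaults are the study
conditions above plus:

* **Prodrome incidence 0.28** per induced animal — 5 deaths among 17
  induced animals. Expected pooled induced survival is therefore 72%, and
  the tests verify Monte-Carlo recovery within ±3 points over 500 cohorts.
* **Event chain**: the death week is drawn first (weeks 8 up to the arm's
  sacrifice), then sign onsets are placed by subtracting the configured
  lags (gain → abdomen ≈ 1 ± 1 week; abdomen → diarrhea 0–2; diarrhea →
  priapism 2–4; priapism → death 1–3, matching the four observed cases).
  Drawing the gain week first and adding lags can push deaths past the
  sacrifice, which would bias simulated survival upward; the backward
  construction keeps every prodrome animal an on-study death, which is what
  the incidence parameter means. Lags are resampled (then clamped) so the
  gain week is at least 3. These lag distributions are loose
  reconstructions from four animals and are configuration, not findings.
* **Growth**: weekly gain is a decaying ponderal-gain percentage (9% in
  week 1 shrinking geometrically to a floor of 2% for controls, 1.2% for
  induced animals, SD 1.5 points) — matching the observed trajectory from
  ~15% during acclimatization to ~2% (sometimes negative) in the week
  before the sudden jump, and giving induced arms the reported final-weight
  deficit. The sudden gain itself is a single-week multiplicative jump with
  PG drawn uniformly from 6–12%, so the recomputed weekly series recovers
  it exactly.
* **Thermography**: back readings are N(31.0, 1.5²) for everyone; abdominal
  readings exist only from the first swollen abdomen observed in the cohort
  (measurement of the disease site started when swelling was first seen)
  and draw from N(32.76, 0.69²) for induced and N(31.05, 1.83²) for control
  animals — the reported group means/SDs used as generator parameters. The
  tests check parameter recovery within two standard errors, not the
  reported significance, because the original per-animal readings are not
  available.
* **Grooming lapses** (score 1 on hair/grooming) occur with weekly
  probability 0.25 in *all* arms after the first injection — lack of
  grooming was the most common finding and the only one shared by control
  animals. Baseline mild findings on a few other parameters occur at 0.02
  per week so that weekly totals are not degenerate zeros.
* One real animal died with no observable pattern; a `sudden_death_hazard`
  knob exists for that but defaults to 0 so the detector-sensitivity
  property (every prodrome animal flagged `high` at least one week before
  death, across 100 seeds) stays exact by construction.

What the simulator does *not* emulate: tumour growth and histopathology,
actual enteritis physiology, inter-observer disagreement (simulated
observations carry a single observer), weight loss from cachexia, and any
correlation between temperature and disease stage beyond the
control/induced split. Passing tests on simulated cohorts therefore show
that the pipeline's logic is correct under the declared data-generating
process, not that the thresholds are clinically optimal.

## Numerical and presentation conventions

Totals and scores are integers; survival rates are presented at 1 decimal
place and group score means at 3; full precision is kept internally and
rounded only for presentation. A single reading in an arm reports SD 0 with
a warning rather than failing, so desk-scale fixtures run. Temperature
readings outside 20–45 °C are dropped with a warning as sensor artifacts.
Weeks are integers with week 1 = first administration; an animal's records
stop at its death or sacrifice week. Problem sizes in the test suite
(1,000 random rubric records, 200 random survival rosters, 500 simulated
cohorts for survival recovery, 100 seeds for detector sensitivity) were
chosen to make Monte-Carlo error comfortably smaller than the asserted
tolerances at desk scale.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from the
installed package alone: the reconstruction survival rates (75.0 / 66.7 /
100 / 100), the death count (5), the log-rank p between induced arms
(> 0.05), the sheet invariants (14 parameters, max total 36, minimal
mandatory-removal total 4), and the simulator-recovery quantities (pooled
induced survival near 72%, abdominal temperature means near 32.76 / 31.05
°C, detector sensitivity 1.0 with its median lead time). All randomness
derives from `--seed`.
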