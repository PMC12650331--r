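---
title: "Threshold alarm patterns before pediatric critical illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold alarm patterns before pediatric critical illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmscape)
library(dplyr)
```

## The problem

Bedside monitors raise a *threshold alarm* whenever a vital sign crosses a
predetermined limit. In pediatric high-dependency care most of these alarms
are non-actionable — transient physiology such as crying or coughing — and
the resulting alarm fatigue erodes the very vigilance the monitors are meant
to support. Yet the alarms that *do* precede a critical illness event (CIE:
death, CPR, transfer to pediatric intensive care, or sepsis) are not random:
their values and durations concentrate in signal-specific ranges in the hours
before the event. alarmscape implements the full analysis chain that turns
raw 1 Hz vital-sign streams into those patterns and into a classifier of
impending critical illness:

1. **Alarm generation** — contiguous threshold-violation episodes in ECG
   heart rate (ECGHR, bpm), ECG respiratory rate (ECGRR, breaths/min) and
   oxygen saturation (SPO2, %), using age-specific cut-offs
   (`builtin_cutoffs()`, `detect_episodes()`).
2. **Temporal windowing** — restriction to the 8 h window before each CIE
   and tallies over four 2 h segments (`window_alarms()`,
   `segment_summary()`).
3. **Pattern clustering** — a from-scratch DBSCAN over each patient's
   alarms in the (value, duration) plane, reduced to modal pattern features
   (`dbscan()`, `extract_pattern_features()`).
4. **Classification** — random-forest, RBF-SVM and decision-tree models on
   per-patient feature vectors, with patient-grouped splits and a
   per-class precision/recall/F1/AUC report (`assemble_dataset()`,
   `train_and_evaluate()`).

Because the clinical recordings this kind of analysis is performed on are
not redistributable, the package carries a first-class synthetic-cohort
generator (`generate_cohort()`) that emulates the monitoring regime, and
every claim the test suite makes is a claim about those synthetic
conditions.

## Alarm generation

Two cut-off tables are built in. Age groups are half-open month intervals;
the WHO table has bands `<1 year`, `1–3 years` and `3–4 years`, and the
GOAL3 table adds `>4 years`. SPO2 has only a lower limit (90% everywhere).

Three decisions fix behaviour the verbal definition of a threshold alarm
leaves open:

* **Strict inequality.** A sample alarms when it is strictly above the
  upper or strictly below the lower limit; values equal to a limit are
  normal. The cut-offs are limits of normality, and "crossing" a limit
  means exceeding it.
* **Gaps terminate episodes.** A missing sample (sensor disconnection) or
  a timestamp gap wider than the sampling interval closes the current run.
  Bridging a disconnection would fabricate alarm duration out of
  unobserved time.
* **Duration and representative value.** Duration is the number of member
  samples times the sampling interval, so a single violating 1 Hz sample
  lasts 1 s and durations add up exactly to the count of violating samples
  (conservation). The representative value of an episode is the median of
  its samples — the signal level during the alarm, robust to spikes — not
  the limit that was crossed.

The WHO top band is extended upward so children older than four years still
resolve to a row (GOAL3 needs no extension). The detector is validated
against a brute-force per-sample scan on a thousand randomised short series
with gaps, and obeys conservation, disjointness and cut-off monotonicity
properties on every case.

## Temporal windowing

Pre-event analysis keeps episodes whose *start* lies in
`[event − 8 h, event)`; the right edge is half-open, and episodes are
assigned to 2 h segments by their start, never split — with most alarms
far shorter than a segment, splitting would change nothing and complicate
the partition invariant (segment counts sum to the window count). Patients
with several events are anchored at the earliest. Event-free patients get
a pseudo-anchor at the recording midpoint (configurable to the last 8 h)
so that their alarm behaviour enters the comparison and the classifier on
the same footing.

## Pattern clustering

`dbscan()` is a classic density-based clusterer written for this package's
small per-group point sets: a *core point* has at least `min_pts` points
(itself included) within Euclidean radius `eps`; clusters are maximal
density-connected sets; everything else is noise. Labelling is
deterministic for a fixed input order — clusters are numbered in order of
discovery and a border point reachable from two clusters joins the lower
id. The implementation is checked against an independent oracle that
materialises the distance matrix and takes connected components of the
core-point graph.

Pattern extraction runs per patient × signal × bound on the
(representative value, duration) plane — the plane in which the clusters
of interest live — after per-dimension standardisation within the group,
so a single unit-free `eps` (default 0.5) works across signals with very
different scales. `min_pts` defaults to 10, the neighbourhood size used in
the originating analysis. Two fallbacks keep sparse data meaningful:
groups with fewer than `min_pts` alarms skip clustering entirely (all
points would be noise), and if clustering still labels everything noise
the whole group is used. The densest cluster is then reduced to its
*modal* value and duration — always observed values, never averages. Mode
ties break to the candidate closest to the median of the summarised
values, then to the smaller value; the tie-break is this package's
convention, since a bare "most frequent value" is undefined on ties (and
on continuous data, where the tie-break effectively selects a central
observed value of the dominant cluster).

Whether clustering should run per patient or pooled per event class is
genuinely open; per patient is the default because the features feed a
per-patient classifier, and pooling is a one-line `group_by` change on the
windowed table.

## Classification

Feature vectors are fixed-width: for each of the five monitored channels
(ECGRR upper/lower, ECGHR upper/lower, SPO2 lower) the modal value, modal
duration, alarm count and a presence flag, with absent channels encoded as
zero + flag — a patient lacking alarms in a channel is information, not
missingness to impute away. Three classes are kept (`none`,
`death_cpr_picu`, `sepsis`): collapsing to death-vs-sepsis would discard
the event-free arm of the balanced design.

Hyperparameters follow the published configuration: random forest with 200
Gini trees of unlimited depth; RBF SVM with `C = 1`, "scale" kernel width
and probability outputs (features standardised with train-set parameters —
RBF kernels need comparable scales; tree models see raw features); a Gini
decision tree grown to full depth; seeds fixed at 42 by default. The split
is 70/30 *by patient*, stratified by class, so no patient contributes to
both partitions. AUC is one-vs-rest per reported class, plus two
averages: a macro average of the per-class AUCs, which sits at 0.5 for a
skill-free classifier whatever the class priors and is therefore the
statistic used in permutation-null checks, and a micro average over
pooled class indicators (a single-curve summary, which tracks priors).
A class absent from the test partition gets `NA` metrics with an attached
note, never a fabricated zero.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the monitoring regime the pipeline is built
for: 1 Hz sampling, ≥24 h records, an age mix of roughly 43% infants and
57% children 1–5 years with a rare neonate, 31%-style CIE prevalence
scaled to a balanced 238-patient design (73:46 death:sepsis mix), sensor
dropout as missing samples (5% default), and brief (<30 s) artifact
excursions beyond the cut-offs at 2 per patient-hour. Baseline physiology
is the midpoint of the WHO normal band for the patient's age, as a bounded
AR(1) process (φ = 0.995, stationary sd 25% of the distance to the nearest
limit) clipped to the band — so an artifact-free, pattern-free patient
never alarms, which makes false-positive tests sharp. Signals are
generated independently; real deterioration couples heart rate,
respiratory rate and saturation, and no such cross-signal structure is
modelled.

CIE patients additionally receive planted alarm patterns in the 8 h onset
window before a randomly placed event time (always ≥8 h after recording
start so the full window exists): a Poisson stream of episodes (default 6
per hour per channel) holding a value drawn uniformly from the published
cluster range of their event type, for a duration around 10 s. Note that
only draws crossing the patient's own age cut-off register downstream —
e.g. an ECGHR value of 155 planted in an infant (upper limit 160) is
silent, and the GOAL3 SPO2 pattern value of exactly 90 never alarms under
the strict-inequality rule against its limit of 90. Recovery tests
therefore target the WHO ranges, where the planted mass crosses the
limits.

Passing tests on this cohort show that the pipeline *recovers what was
planted under realistic noise, dropout and artifacts* — they do not show
that real pediatric monitoring data contain such patterns, and the
published real-data accuracies cannot be recomputed without the clinical
dataset. The package instead emits the same report schema, so real data
can be dropped in unchanged.

## Numerical choices and problem sizes

* Determinism everywhere: cohort generation, balancing, splitting and
  model fits are seeded; the pipeline derives stage seeds as master seed +
  stage ordinal so stages re-run independently.
* The test suite exercises the study-scale conditions once (238 patients ×
  24 h × 1 Hz ≈ 20.6 M samples per signal stream set) and shares that
  fixture across the pattern-recovery and classifier checks; oracle
  comparisons use 1,000 series of ≤50 samples and 200 random point sets of
  ≤40 points, sizes at which brute force is exact and instant.
* Percentages in alarm summaries are rounded to the nearest integer,
  matching the tabulation convention of the counts they are checked
  against.

## Known limitations

* No alarm debouncing: violations separated by a single in-range sample
  are distinct episodes. If the source analysis merged such runs its
  counts would differ.
* Blood pressure and temperature channels, audible-alarm policy and
  real-time detection are out of scope.
* The synthetic generator is a test harness for the pipeline, not a
  physiological simulator: no waveform morphology, no inter-signal
  coupling, no circadian structure.
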