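---
title: "Active case finding for six-month ED utilization risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active case finding for six-month ED utilization risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emergency department (ED) visits are frequent, expensive, and often
preventable. Population health teams — rather than waiting for an index event —
want to score an *entire* insured or regional population ("active case
finding") and direct outreach to the people most likely to visit an ED soon.
`edcasefinder` implements such a pipeline end to end: it turns a year of
encounter-level clinical history (visits, diagnoses, laboratory results,
radiology, outpatient prescriptions) into a patient-level feature matrix,
learns a hybrid risk model for *any ED visit in the following six months*,
calibrates the model's raw score to a 0–100 risk index with positive
predictive value (PPV) semantics, evaluates discrimination and time-to-event
separation, and phenotypes the resulting high-risk population.

Real statewide health-information-exchange (HIE) extracts cannot be shipped
with a package, so a seeded synthetic generator with a known ground-truth risk
structure stands in for them. Everything downstream of the generator treats its
output exactly like imported CSV tables.

## The model

### Feature engineering

Records are pivoted to one numeric row per patient. Count features are used
for encounter types, primary and secondary diagnoses, laboratory tests
(total and abnormal counts per test), radiology modalities, and medication
classes; indicator features for the four age groups (0–18, 19–34, 35–49, 50+,
lower edges inclusive), gender, and the chronic diagnosis-chapter categories.
Absence is encoded as zero, never `NA`, so a patient with no history is a valid
(all-zero) row — the "new patient" case, which the model deliberately scores
from demographics alone. Two rules guard temporal hygiene: features are
computed only from the 12-month observation window, outcome and time-to-event
only from the 6-month outcome window; tests assert that deleting or permuting
outcome-window records leaves the feature matrix bit-identical.

Each ICD-9-style diagnosis code is dichotomized chronic/non-chronic through a
bundled lookup in the spirit of the AHRQ Chronic Condition Indicator. The
bundled table is synthetic (26 codes across six chapter families); unknown
codes default to non-chronic with a warning, a conservative choice that avoids
inflating the chronic stratum.

An optional variance filter min-max scales every feature to [0, 1] — so counts
and indicators compete on one scale; the data do not dictate a scale — and
keeps the `keep_n` highest-variance columns, with ties broken by name and the
two empirical routing features (`prior_ed_count`, `chronic_flag`) always
retained. The filter is idempotent.

### Cohorts

Patients who died (any encounter with disposition `expired`) are excluded;
same-day ED-to-ED transfer records are merged into a single visit. The
analyzable population is stratified into six cells — chronic history
(yes/no) × prior-year ED band (0, 1, ≥2) — and, within each cell, cases and
controls are separately shuffled and dealt round-robin to Cohort I (training),
II (calibrating) and III (blind testing). Dealing, rather than independent
random assignment, makes the balance guarantee exact: per stratum and
case/control arm the three cohorts differ by at most one patient. The six-cell
operationalization crosses the two factors the empirical partition uses; the
third factor mentioned alongside them (current primary diagnosis) is checked
for balance post hoc rather than used as a splitting axis, which would explode
the cell count.

### The hybrid learner

Two *empirical* features — any prior-year ED visit, any chronic diagnosis —
drive a deterministic 2×2 partition of the cohort into four subgroups. Within
each subgroup:

1. **Feature selection.** Greedy forward selection picks the minimal feature
   set: at each step the candidate maximizing out-of-fold *sensitivity* within
   the top `review_fraction` of scored patients is added, restricted to
   candidates meeting the PPV target (default 70%) in that slice whenever any
   candidate attains it. Candidate sets are scored by 5-fold out-of-fold
   logistic scores (`glm.fit`) rather than by refitting the forest per
   candidate: the selection criterion needs only a score *ranking*, the
   logistic surrogate is two orders of magnitude cheaper, and out-of-fold
   scoring avoids the optimism an in-sample PPV estimate would leak into the
   stopping rule. Selection stops when the marginal sensitivity gain drops
   below `tol` (default 0.002) or at `max_features` (default 12). Ties prefer
   the lexicographically smaller name, making selection fully deterministic.

2. **Survival forest.** A bagged ensemble (default 100 trees, bootstrap
   fraction 0.8, depth ≤ 8, ≥ 25 patients per leaf) of survival trees grown on
   (time-to-first-ED, event) restricted to the 180-day horizon. Splits maximize
   the two-sample log-rank statistic; each leaf predicts its empirical 180-day
   event fraction, and the forest score is the mean over trees — so the score
   is a posterior probability of a 6-month ED visit, not a hazard. A plain
   classification mode (Gini splitting on the event indicator) sits behind
   `split_rule = "gini"` for comparison. Tree growth is implemented in C++;
   candidate thresholds per feature are capped at 15 evenly spaced midpoints
   of the sorted unique values, which is exact for count features (few unique
   values) and a standard discretization for continuous ones. The in-tree
   log-rank statistic is cross-checked against `survival::survdiff()` in the
   test suite.

A degenerate subgroup (one outcome class, or no usable features) yields a
constant model emitting its event fraction, so scoring is total. Scoring
routes by feature *name*, never column position; a feature absent from new
data is treated as zero, except in prospective mode where a schema check
raises an error naming the missing columns first.

### PPV calibration

On Cohort II, for each distinct raw score *s* the empirical
PPV-above-threshold is `100 × #(cases with score ≥ s) / #(score ≥ s)`. A
running maximum from the lowest score upward makes the curve monotone, and
linear interpolation between the resulting knots maps any raw score to a 0–100
index. This is the lightest construction that satisfies the index's defining
semantics: patients with index ≥ L have approximately an L% probability of an
ED visit within six months. On the calibration set the identity is exact at
every attained index (a property test asserts it); held out, it is
approximate — the acceptance suite requires the PPV among patients with
index ≥ L to lie within ±5 points of L for L ∈ {30, 50, 70}.

Two details. Knot PPVs are estimated only where at least `min_cell` (default
50) patients lie at or above the knot; sparser high-score tails inherit the
nearest valid knot's index, trading a little resolution for variance control.
And the low/medium/high thresholds live on the 0–100 index scale with
inclusive lower bounds: low < 30 ≤ medium < 70 ≤ high.

### Evaluation

The blind-test report contains the ROC AUC (threshold sweep + trapezoid,
verified against O(n²) pair counting to 1e-12), the PPV table at index
thresholds {30, 50, 70, 80}, Kaplan–Meier curves per risk group with a k-group
log-rank test (both via the `survival` package), mean outcome-window ED visit
counts per group, and shrunken differences. The shrunken difference follows
the nearest-shrunken-centroid construction:
`d = (class mean − overall mean) / (m_k (s_j + s0))` with `s_j` the pooled
within-class SD, `s0` the median of all `s_j`, `m_k = sqrt(1/n_k + 1/n)`, and
optional soft-thresholding of `|d|` (default shrinkage 0 — it is used as a
diagnostic display, not a classifier).

### High-risk phenotyping

Patients with index ≥ 70 (inclusive, matching the risk-group boundary) are
standardized, projected onto the fewest principal components reaching 80%
cumulative explained variance, and clustered by K-means with K = 6. K-means
uses greedy farthest-point seeding (first center a seeded random row, each
subsequent center the point farthest from those chosen) with 25 restarts,
keeping the lowest within-cluster sum of squares — deterministic given the
seed. All model features feed the projection by default; profiles report per
cluster the age/gender composition, chronic chapter prevalences as explicit
n/N fractions, and mean laboratory / radiology / prescription counts, ordered
by cluster size.

## The synthetic generator

The generator emulates the structural features of a statewide HIE extract that
the pipeline depends on:

* **Marginal incidence.** Each patient's 6-month ED event probability is a
  logistic function of five drivers — capped prior-year ED count, chronic
  flag, ordinal age band, capped medication count, number of chronic
  categories — and the intercept is calibrated by root finding so the
  population mean equals the target incidence (default 11.5%).
* **ED recurrence.** The default driver weights make repeat ED use strongly
  prognostic: among patients with ≥ 2 prior-year ED visits, more than 80%
  revisit within the 180-day outcome window. This is a design constraint of
  the default configuration, not an emergent accident, and a test holds it.
* **Risk-ordered event times.** Event days are drawn as
  `180 · U^(1 + 2·hazard)`, so higher-risk patients tend to earlier events,
  giving the Kaplan–Meier separation by risk group a ground truth to recover.
* **Correlated utilization.** A Gamma frailty couples a patient's encounter,
  laboratory, medication and radiology intensities, and chronic patients draw
  their visit diagnoses mostly from their own chronic codes, so the coded
  chronic flag tracks the latent one.
* **Exclusion fodder.** A configurable fraction of patients carries an
  `expired` disposition and a fraction of ED visits a same-day
  `transfer_from_ed` twin, exercising the exclusion/merge rules.

All randomness flows through one seeded generator (`withr::with_seed`), so an
identical configuration reproduces byte-identical tables and the global RNG
stream is left untouched. The latent `truth_hazard` is persisted in a separate
ground-truth file and never exposed to the model.

What the generator does *not* emulate: real ICD-9 code frequencies, payer mix,
seasonal patterns, regional demographics, coding errors, or missingness
mechanisms beyond absence. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind it is designed for* from data *known
to contain it* — they say nothing about performance on any real population.

## Problem sizes and numerical choices

The bundled study runs at 20,000 patients (the acceptance suite and
`scripts/acceptance.R`), with 50,000 used for the Monte-Carlo checks of the
generator's marginal incidence (±1 percentage point) and recurrence targets.
These sizes put roughly 6,600 patients in each cohort and several hundred in
the high-risk tail — enough for the held-out PPV checks (binomial SE ≈ 2
points at index 70) while a full end-to-end run stays around half a minute.

Other numerical choices worth stating: min-max scaling precedes the variance
filter; greedy-selection ties break lexicographically; split-candidate
thresholds cap at 15 per feature per node; forest bootstrap draws are with
replacement at 80% of subgroup size; the permutation null for the
discrimination check permutes outcomes across the *whole* dataset and re-runs
split and training in that null world (permuting only the training labels
would leave the four subgroup score levels colliding with wildly different
true event rates, making the null AUC high-variance for reasons unrelated to
leakage); calibration interpolation clamps outside the knot range; K-means
restarts vary only the seeded first center.

## A worked run

```{r, eval = FALSE}
library(edcasefinder)

cfg <- run_config(
  synth = synthetic_config(n_patients = 20000, seed = 11),
  seed = 11, out_dir = "ed-run")
res <- run_retrospective(cfg)

res$evaluation$auc          # blind-test discrimination
res$evaluation$ppv_table    # PPV at index 30/50/70/80
res$clusters$profiles       # six high-risk phenotypes
```

The artifact directory then holds `model.json` (partition rule, per-subgroup
feature lists, serialized trees, calibration map), `assessments.csv`
(patient, raw score, index, risk group), `evaluation.json`, `profiles.csv`,
`cohorts.csv`, `exclusions.csv`, and `manifest.json`, whose hash is embedded
in the report so two runs with equal manifests produce equal artifacts. A
frozen model is applied to a new cohort with `run_prospective()`, which scores
without refitting.

## Known limitations

* The feature taxonomy is a small stand-in; real deployments would map LOINC,
  RxNorm and the full AHRQ CCI table, which is out of scope here.
* The risk index's PPV semantics are exact on the calibration cohort and only
  approximate out of sample; drift between cohorts shows up directly as a
  PPV-vs-index gap.
* The greedy selector optimizes sensitivity under a PPV constraint with a
  logistic surrogate; features whose value appears only in interaction with
  others inside the forest can be missed.
* Survival handling is restricted to the 180-day horizon with administrative
  censoring only; there is no competing-risk treatment of death (deaths are
  excluded upstream).
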