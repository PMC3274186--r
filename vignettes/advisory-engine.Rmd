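---
title: "The blood-glucose advisory engine: models, rules and the KNN recommender"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The blood-glucose advisory engine: models, rules and the KNN recommender}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucadvisor)
```

## What the engine does

`glucadvisor` implements the decision core of a blood-glucose
self-management advisory system for diabetes patients. Given a
time-stamped observation record — hour of day, blood sugar (mg/dL),
systolic and diastolic blood pressure (mmHg), energy spent on exercise
and consumed in meals (kcal), and the patient's daily calorie target —
the engine recommends one of five treatment actions:

| code | action |
|------|--------------------------|
| 1 | more exercise |
| 2 | eat more (a meal or snack) |
| 3 | emergency (rest) |
| 4 | take insulin |
| 5 | normal (maintenance) |

Two recommenders are provided and can be compared on the same labeled
data: a time-windowed threshold **rule engine**, and an instance-based
**k-nearest-neighbor (KNN) classifier** with optional min–max feature
normalization. A calorie module computes the daily target that feeds the
record, and a seeded synthetic generator makes the whole pipeline
testable without patient data.

## The calorie model

The daily calorie target starts from the *standard weight*,

$$ w_\mathrm{std} = h^2 \cdot c_\mathrm{sex}, $$

with height $h$ in meters and $c_\mathrm{female} = 21$. For a 1.65 m
woman this gives $1.65^2 \times 21 = 57.1725$ kg. The companion male
constant 22 is the conventional one for this formula; the worked example
the module reproduces is female-only, so the male factor is documented
as an extrapolation and is overridable via the `factors` argument.

The standard weight is rounded **up** to whole kilograms — the only
rounding rule consistent with 57.1725 kg being treated as "about 58 kg"
— and multiplied by an activity-dependent rate:

| activity | kcal/day per kg |
|----------|-----------------|
| light    | 25–30 |
| normal   | 30–35 |
| hard     | 35–40 |

Each band is a range; `band_point` (default 0, i.e. the lower bound,
which reproduces the canonical 58 kg × 25 = 1450 kcal/day example)
selects a position inside it. The target is monotone in weight, activity
class and band point, and the test suite asserts all three
monotonicities.

```{r}
calorie_target(1.65, "female", "light")
```

## The diagnostic grid

`diagnose_glucose()` classifies a fasting plasma glucose (FPG) reading,
together with the blood sugar 2 h after a meal, into `normal`,
`abnormally_high`, `IGT` (impaired glucose tolerance), `IFG` (impaired
fasting glucose) or `low`. The low row (FPG below 70 mg/dL) needs no
post-meal value and dominates the others. The grid is deliberately not
total: combinations it does not cover (say FPG 110 with post-meal 250)
return `"unclassified"` rather than guessing — a clinical grid should
not silently extrapolate.

## The rule engine and its precedence order

The packaged rule set (`default_ruleset()`) assumes meals at 7:00,
12:00 and 18:00 and sleep at 24:00, giving three families of
time-windowed rules plus two always-active ones:

1. **emergency** (any hour): blood sugar below 70 mg/dL → rest;
2. **fasting windows** 0–7, 9–12, 14–18, 20–23: over 126 mg/dL → more
   exercise;
3. **before sleeping** 22–24: below 120 mg/dL → eat more;
4. **4 h after meals** 9–12, 15–17, 20–23: over 140 mg/dL → more
   exercise; below 100 mg/dL → eat more;
5. **always**: over 180 mg/dL → take insulin;
6. otherwise → maintain.

The numbered order *is* the precedence: the first rule whose window
contains the record's hour and whose strict threshold comparison holds
wins. Three design choices deserve a note, because the source tables
alone do not fix them:

* **Window rules outrank the always-insulin rule.** A fasting reading
  of 199 mg/dL at 7:00 must yield "more exercise", not "take insulin",
  to match the published example records; clinically, persistent highs
  in fasting windows are managed by exercise first, with insulin
  reserved for highs the windows do not explain.
* **The emergency rule outranks everything**, at every hour. A sweep
  test over all hours 0–24 and blood sugars 0–400 asserts both totality
  (a code in 1..5 everywhere) and this dominance.
* **Bounds are inclusive, thresholds strict.** Hours 8, 13 and 19 fall
  in no window and are governed only by the always-rules; blood sugar
  exactly 100 at 23:00 does not trigger "below 100" but does trigger the
  before-sleep "below 120".

Rule sets are data (`treatment_rules()`), so alternative precedence
hypotheses can be expressed and tested without code changes.

Two of the ten packaged example records carry labels that no rule in the
set can produce at their hours (both fall at hours outside every window);
they appear to have been labeled independently of the rules. They are
retained in the fixture — they are part of the published data — but
excluded from rule-agreement tests, and they are one reason a rule
engine scored against independently assigned labels cannot reach perfect
agreement.

## The KNN recommender

The KNN classifier stores a labeled sample (training) set as memory. A
query record is compared with every sample record by Euclidean distance
over the seven features,

$$ d(x, y) = \sqrt{\sum_{r=1}^{7} (a_r(x) - a_r(y))^2}, $$

and the plurality label among the $k$ nearest records is recommended.
Since the square root is monotone, every KNN answer is identical whether
distances or squared distances are ranked; a test asserts this vote
invariance explicitly.

Determinism requires two explicit tie rules:

* **Selection ties** (equal distances at the k-th position): sample
  records are taken in stable dataset order.
* **Vote ties** (possible for $k = 3$ with three distinct labels, and
  for $k = 5$): the tied code backed by the single nearest neighbor
  wins, so behavior degenerates gracefully to $k = 1$.

### Min–max normalization

Raw Euclidean distance is dominated by whichever features span the
widest ranges — here the calorie columns, spanning thousands of kcal,
against the time column's 24 hours. The normalized mode rescales each
feature with bounds fitted on the **sample set only**:

$$ z = \frac{x - \min_\mathrm{sample}}{\max_\mathrm{sample} - \min_\mathrm{sample}}, $$

clamped to $[0, 1]$, so test values outside the sample's span saturate
at 0 or 1. The treatment label is never normalized. A degenerate feature
(sample max = min) maps to 0 and so contributes nothing to any distance.
The package reconstructs the published normalized example table
cell-for-cell at the printed precision from these rules, with two
documented exceptions: one blood-sugar cell is a misprint
(inconsistent with the bounds that reproduce the other nine cells of its
column), and the target-calories column's bounds cannot be recovered
self-consistently from the printed values, so that column is checked
only for clamping behavior.

## The evaluation harness

`score_predictions()` scores a recommender by elementwise match: 1 where
the predicted code equals the label, 0 otherwise, summarized as a match
count and an accuracy fraction. `compare_methods()` runs the rule engine
and the KNN classifier — raw and normalized, for each requested $k$ — on
one test set against one sample set and tabulates all configurations.
The comparison is deterministic given its inputs.

The original experiments behind this design used a 200-record sample set
and a 100-record test set that were never published; their headline
match counts (rule-based 42/100; raw KNN 36, 52, 64 for k = 1, 3, 5;
normalized KNN 61, 65, 61) are therefore context, not test oracles. The
package replaces them with properties that *are* checkable: exhaustive
brute-force agreement of the KNN route, exact rule-engine agreement on
rule-consistent labels, the binomial behavior of label noise, and the
average superiority of normalized over raw KNN on scale-imbalanced data
— the qualitative finding that motivated normalizing in the first place.

## The synthetic generator

`generate_records()` draws seeded sample/test sets shaped like the
published example records. Design choices:

* **Uniform marginals** within per-feature ranges defaulting to the span
  of the published records (time 5–23 h, blood sugar 50–423 mg/dL,
  systolic 100–180, diastolic 50–100 mmHg, exercise 0–500, meal 0–680,
  target 150–2439 kcal). Nothing is known about the real data's
  distribution, so the flattest assumption is used.
* **Systolic > diastolic** is enforced by drawing diastolic below the
  record's systolic.
* **At most one of exercise/meal is nonzero** per record, mirroring the
  three observation modes (a normal reading, an after-exercise reading,
  an after-meal reading), each equally likely.
* **Labels come from the packaged rule set.** In `rule_consistent` mode
  they are kept, so the rule engine scores 1.0 by construction — a
  calibration check. In `noisy` mode each label flips with probability
  `noise_p` to a uniformly random different code, emulating labels
  assigned independently of the rules; the rule engine's expected
  accuracy is then $1 - p$, and a binomial test asserts this at
  a thousand records.

What the generator does **not** emulate: physiological glucose dynamics,
meal-response curves, correlation between features (beyond the two
structural constraints), or any demographic structure. Passing tests on
synthetic data therefore demonstrate the correctness of the *machinery*
— parsing, rules, distances, votes, scoring — not clinical performance
on real patients.

## Numerical choices and problem sizes

* Normalized-table reconstruction is asserted at an absolute tolerance
  of $10^{-3}$ — agreement at the three printed decimals. The published
  table mixes rounding and truncation in its last digit, so exact
  3-dp rounding equality is not a meaningful target.
* Brute-force KNN agreement is checked on randomized datasets of up to
  50 records, for $k \in \{1, 3, 5\}$, raw and normalized.
* The normalization-benefit check averages accuracies over 20 seeded
  replicates of 150 sample / 75 test records whose labels depend on all
  seven features through their range-scaled mean — sizes at which the
  tendency is stable while the whole suite stays fast.
* The rule-engine sweep covers the full unit grid of hours 0–24 ×
  blood sugar 0–400.

## Limitations

* The rule set encodes one fixed daily schedule (meals 7:00/12:00/18:00,
  sleep 24:00); patients on other schedules would need a custom
  `treatment_rules()` object.
* Time is treated as a linear coordinate in the KNN distance, not a
  circular one: hours 23 and 1 are 22 apart, not 2. The published
  distance formula implies exactly this, and all example records lie
  within 5–23 h, but it is a modeling limit worth knowing.
* Insulin *dosage* is out of scope; the engine emits action codes only.
* The diagnostic grid and treatment thresholds are fixed clinical
  constants from the source tables, not tunable parameters.
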