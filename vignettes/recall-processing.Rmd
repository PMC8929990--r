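---
title: "Processing 24-hour dietary recalls: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing 24-hour dietary recalls: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recall24)
```

## The processing model

Tablet-based 24-hour recall tools used in East African field studies export
each interview as two delimited tables: a *demographics* table with one
record per participant per recall day (age, sex, day characterization,
supplement use, declared breastfeeding frequency) and a *meals* table with
one record per food, snack or beverage consumed (clock time, location, food
code or sentinel code, utensil and portion report, breast-milk flag, free
text). `recall24` turns that export into per-meal and per-person-day
nutrient intakes and meal-structure analytics.

The chain for one food entry is

$$
\text{grams} = \text{portion count} \times g(\text{key}), \qquad
\text{nutrients} = \frac{\text{grams} \times \text{EP}}{100}
  \times \mathbf{v}_{100},
$$

where $g(\text{key})$ is the grams-per-unit weight of the matched portion
key, EP is the food's edible fraction, and $\mathbf{v}_{100}$ is its
per-100 g nutrient vector (energy, protein, animal-source protein, fat,
carbohydrate, fiber, calcium, iron, zinc, vitamin A in retinol
equivalents, folate). Person-day totals are the componentwise sum over
non-excluded entries. Breast-milk entries carry timing and location only
and are never included in nutrient estimates; unresolved foods contribute
zero and are counted per day rather than failing the day.

### Code resolution

Food codes are resolved by a deterministic cascade that mirrors the manual
post-collection review workflow: (1) a code found in the primary
food-composition table resolves directly; (2) the unknown-meal sentinel
`9999` resolves through an explicit, human-edited assignment table (keyed
by entry id, falling back to the meal description) to a primary code, a
secondary-table code, or a registered recipe; (3) the new-recipe sentinel
`8888` resolves to a registered recipe; (4) anything else is unresolved,
with the path taken recorded in an audit string. There is deliberately no
fuzzy text matching: the assignment file is a reviewable artifact, and a
wrong silent match is worse than an explicit unresolved count. A
consequence worth knowing: a *non-sentinel* code that is absent from the
primary table is unresolved — secondary-table foods are reachable only
through assignments, matching the review workflow in which only flagged
unknown meals are checked against the secondary reference.

### Recipe nutrients per 100 g

For a recipe with ingredients $(\text{grams}_i, \text{EP}_i,
\mathbf{v}_{100,i})$ and yield $W$,

$$
\mathbf{v}_{100}^{\text{recipe}}
  = \frac{100}{W} \sum_i \frac{\text{grams}_i \times \text{EP}_i}{100}
    \, \mathbf{v}_{100,i},
$$

with $W$ the recorded cooked weight when present and the raw ingredient
total otherwise (a message notes that the moisture change of cooking is
then ignored). No nutrient retention factors are applied: locally specific
factors are generally unavailable for these cuisines, and applying generic
ones would give a false sense of precision. Two consequences are used as
test oracles: the vector is invariant to scaling all masses and the yield
by any $k > 0$, and without a cooked weight each component is a weighted
mean of the EP-scaled ingredient components, hence bounded by their
extremes.

### Edible-portion convention

Per-100 g values in a food-composition table refer to 100 g of *edible
portion*. The package therefore applies the edible fraction when
converting as-served grams — at intake computation for whole foods, and to
raw ingredient masses inside recipes. Reference tables mark such foods
(e.g. fruit weighed with peel) but do not state the arithmetic; this
convention is a package decision, applied uniformly and documented here so
it can be audited. The recipe yield denominator is the as-recorded mass
(cooked weight, or raw total), not the EP-reduced mass, because the yield
is what the cook weighs.

## Portion conversion

Portion keys are `(food code or food group, utensil, size)` with gram
weights per serving unit; densities are baked into the gram estimates
rather than modeled volumetrically, because field portion databases ship
gram weights for the utensils used as interview aids (bowl, cup, tumbler,
plate, tablespoon, teaspoon, saucer — three size classes each).
Food-specific entries always beat food-group defaults. A missing mapping
is an error by default; `portion_fallback_g` downgrades it to a warning
with a configurable default, because real field datasets contain gaps and
a monitored fallback beats a crashed batch.

## Quality-control rules

`validate_recall()` emits findings independently per rule; severities are
chosen so that only internally inconsistent interviews are errors.

* **BF_MISMATCH** (error): the declared breastfeeding frequency must equal
  the number of breast-milk meal entries — the interview enforces this
  consistency, so a mismatch means a data-entry fault.
* **TWO_MORNINGS** (warning): the export carries clock times without
  dates, so a recall that spans two mornings (e.g. 08:00 yesterday to
  08:00 today) is detected heuristically: entry times in recorded order
  decrease somewhere, with a time before the morning cutoff (default
  10:00) on both sides of the decrease. This is a heuristic and is
  documented as such; it cannot distinguish a genuine two-morning recall
  from an out-of-order morning correction.
* **TIME_GAP** (warning): one finding per gap between consecutive meal
  groups exceeding `max_gap_minutes` (default 360). Six hours flags the
  long daytime gaps an interviewer should probe, while tolerating the
  overnight-free window of a single-day recall.
* **IMPLAUSIBLE_PORTION** (warning): converted grams above an age-class
  threshold. Published sources give only qualitative examples (8 cups of
  cooked rice for a 13-month-old), so the thresholds are a configurable
  table; the shipped defaults (infant 800 g, child 1500 g, adult 3500 g
  per entry) are set an order of magnitude above typical single-entry
  gram weights in the bundled portion data.
* **UNAVAILABLE_FOOD** (warning): foods outside an optional regional
  availability list (e.g. strawberries in a remote inland region); no
  default list ships because availability is study-specific.

Findings depend only on `entry_index` order, never on file row order, so
permuting export rows cannot change the finding multiset.

## Meal grouping and chrono-nutrition

A *meal* is any set of foods, snacks and beverages consumed at the same
time. Grouping is single-linkage on sorted clock times with a tolerance
that defaults to 0 minutes (identical recorded times), because the
interview records one time per sitting; the tolerance is configurable for
instruments that timestamp items individually. Meal order is the
per-person-day rank by time and is reported positionally (meal 1, 2, ...)
rather than as breakfast/lunch/dinner, since the labels are culturally
loaded and analytically unnecessary. Weekday labels derive from the recall
date by ISO weekday number with a fixed English mapping, independent of
locale.

The food-away-from-home (FAFH) share of a person-day is away-from-home
energy over total energy, computed at the entry level (each entry carries
its own location), undefined — not an error — on zero-energy days. The
cohort summary reports the median share among person-days with at least
one away meal record, conditioning as the corresponding field summaries
do, plus the distribution of meal records by location.

## Reference tables

Only the constants that are fixed points of the package are hard-coded:
the breastfed acceptable energy ranges (100–600 kcal at 6–8 months,
200–750 at 9–11, 500–1100 at 12–23, inclusive at both ends) and the
breast-milk-adjusted folate RNI of 27.6 μg/d for 9–11 months. The
adjusted folate value is stored as a constant because its derivation is
not published. The remaining RNI rows ship as editable defaults in the
magnitude range of the UN references (iron at 10% bioavailability, zinc
at moderate bioavailability) and are intended to be replaced by the
study's authoritative table. Ranges for non-breastfed children are not
shipped at all: published acceptable-intake analyses apply them without
printing them, and inventing defaults would be worse than requiring
explicit user input.

```{r constants}
energy_range_table_default()
subset(rni_table_default(), nutrient == "folate_ug")
```

## The synthetic-data generator

The generator emulates the *structure* of the two study populations, not
their nutrient distributions: an adult cohort (75% female, 3–4 meals a
day at morning/midday/evening modes, men far more likely to eat away from
home) and a child cohort (age bands weighted 83/360/262/140 per 845, with
age-graded breastfeeding probabilities 100/97.5/78/39% and frequency
medians 7/5/4/0, meal counts that fall with age). Mock food-composition
tables cover ten food groups with group-plausible nutrient ranges,
edible fractions below 1 for peeled foods, and a portion database that
covers every food through group defaults plus a few food-specific
overrides so the precedence rule is exercised.

Specific calibrations worth recording:

* **Timing modes.** Urban adult meals in the motivating setting cluster
  near 09:00, 13:00–14:00 and 20:00–21:00. A 13:30→20:30 gap is 420
  minutes, which the default QC rule would flag on perfectly clean data.
  Since the generator's contract is that clean output passes validation
  with zero findings, its default evening mode is 18:15 and a
  gap-compression pass caps clean consecutive-meal gaps at 340 minutes.
  The timing-mode recovery check therefore tests the generator's own
  configured modes, which is the honest comparison.
* **FAFH targeting.** Away meals are the first one (women) or two (men)
  meal groups of the day, matching the observation that eating out is a
  morning-and-lunch phenomenon; portion counts of away meals are rescaled
  so each away-eating person's away-energy share matches the configured
  per-sex target (scale factor capped at [0.05, 2.5] to keep portions
  plausible). This makes median-share recovery a sharp parameter-recovery
  check instead of a coarse subset artifact.
* **Sentinel usage.** A configurable fraction (default 3%) of food
  entries is recorded as code 9999 with the true code (or a
  secondary-table food) stored in the returned assignment map, emulating
  the unknown-meal review loop.
* **Fault injection** rewrites sampled recalls to violate exactly one
  rule each — incrementing the declared breastfeeding frequency, appending
  an early-morning entry after the evening meals, inflating one portion
  count, or stretching one inter-meal gap — on disjoint recalls, and
  returns the ground-truth list so the validator's finding multiset can
  be compared exactly.

What passing tests on synthetic data do **not** show: robustness to
free-text code corruption, to portion databases with systematic gaps, to
multi-day exports, or to the nutrient distributions of any real cohort.
The generator's nutrient ranges are group-plausible, not estimated.

## Numerical choices and problem sizes

All arithmetic is double precision; the pipeline-versus-oracle comparison
is held to 1e-9 relative tolerance and lands at machine precision because
both paths perform the same sums in different orders. Range endpoints are
inclusive. Ties in meal grouping are broken by entry index, and food
frequency ties alphabetically, so all reports render deterministically.
The test suite and the acceptance script size their cohorts at 120
person-days for the oracle comparison, 200 for fault recovery, and 500
adults for analytics recovery — sizes at which the recovery tolerances
(±0.05 on median shares, ±30 minutes on timing modes) are comfortably
testable while the whole suite stays fast on one CPU.

## Known limitations

* Supplement use is carried as a flag; supplement nutrient contributions
  are not modeled.
* No usual-intake modeling or within-person variance deconvolution; the
  unit of analysis is the person-day.
* Recipe nutrients ignore retention factors and, without a cooked weight,
  moisture change.
* The two-mornings heuristic and the implausibility thresholds are
  screening aids, not validated classifiers.
* The breast-milk-adjusted folate RNI is a stored constant; its
  derivation is not reproduced.
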