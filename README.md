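# recall24

Back-end processing and analytics for **tablet-based 24-hour dietary
recall** data, as collected in East African field studies among adults and
young children.

Quantitative dietary assessment in low- and middle-income settings
produces a characteristic two-table export per interview: a
*demographics* table (one record per participant per recall day) and a
*meals* table (one record per food, snack or beverage, with clock time,
location, food code, utensil-based portion report and a breast-milk
flag). Turning that export into nutrient intakes requires linking food
codes to food-composition tables (FCTs), resolving the sentinel codes used
for unknown meals (`9999`) and new recipes (`8888`), converting utensil
portions to grams, and applying the interview's consistency rules.
`recall24` implements that entire back end, for field teams running daily
data-quality monitoring and for analysts computing intakes and
meal-structure summaries.

## The core computations

For a food entry with portion count $c$, matched portion weight $g$
(grams per unit; food-specific keys take precedence over food-group
defaults), edible fraction $\mathrm{EP}$ and per-100 g nutrient vector
$\mathbf{v}_{100}$:

$$\text{nutrients} = \frac{c \, g \, \mathrm{EP}}{100}\,\mathbf{v}_{100}$$

over the 11 reported nutrients (energy, protein, animal-source protein,
fat, carbohydrate, fiber, calcium, iron, zinc, vitamin A as retinol
equivalents, folate). Person-day totals sum the non-excluded entries;
breast-milk entries contribute timing only. Unknown codes resolve through
a deterministic cascade (primary FCT → explicit assignment to a primary
or secondary code or to a recipe → unresolved, fully audited), and recipe
nutrients per 100 g are
$\tfrac{100}{W}\sum_i \mathrm{grams}_i\,\mathrm{EP}_i\,\mathbf{v}_{100,i}/100$
with $W$ the cooked weight (or raw mass when unrecorded), without
retention factors.

On top of the intakes, the package provides the interview QC rules
(breastfeeding-frequency consistency, two-mornings detection, meal time
gaps, implausible portions, regional availability), field reports and
per-person dietary profiles, and chrono-nutrition analytics: meal
grouping ("consumed at the same time" = one meal), meal frequency with
and without breastfeeding, energy by meal-order position, food-away-from-
home (FAFH) energy shares, food frequency rankings, meal-timing
histograms, RNI adequacy ratios and acceptable energy-range
classification for breastfed children (100–600 kcal at 6–8 mo, 200–750
at 9–11 mo, 500–1100 at 12–23 mo). A seeded synthetic-cohort generator
emulates the export for testing, training and calibration.

## Worked example

```r
library(recall24)

fct <- fct_table(tibble::tibble(
  code = c("101", "102", "103"),
  name = c("maize ugali", "beef relish with oil", "mango ripe"),
  food_group = c("cereals", "meat", "fruits"),
  edible_fraction = c(1, 1, 0.7),
  energy_kcal = c(112, 220, 60), protein_g = c(3, 18, 0.5),
  animal_protein_g = c(0, 18, 0), fat_g = c(0.5, 15, 0.3),
  carb_g = c(24, 1, 15), fiber = c(1.2, 0, 1.8), calcium_mg = c(8, 15, 11),
  iron_mg = c(0.6, 2.1, 0.2), zinc_mg = c(0.9, 4.5, 0.1),
  vitA_ug_RE = c(0, 10, 54), folate_ug = c(18, 8, 43)))

db <- portion_db(tibble::tibble(
  food_code_or_group = c("cereals", "meat", "fruits"),
  utensil = "plate", size = "medium",
  grams_per_unit = c(350, 120, 150), provenance = "study portion database"))

demog <- tibble::tibble(
  participant_id = "A001", recall_date = as.Date("2019-03-12"),
  cohort = "adults", age_value = 41, age_unit = "years", sex = "male",
  day_character = "typical", supplement_use = FALSE,
  declared_bf_frequency = 0L)

meals <- tibble::tibble(
  participant_id = "A001", recall_date = as.Date("2019-03-12"),
  entry_index = 1:3, clock_time = c(540L, 800L, 1110L),
  location = c("mamalishe", "home", "home"),
  food_code = c("101", "102", "101"),
  description = c("maize ugali", "beef relish with oil", "maize ugali"),
  ingredients = "", utensil = "plate", utensil_size = "medium",
  portion_count = c(1, 1, 1.5), is_breastmilk = FALSE, comments = "")

recall <- assemble_recalls(demog, meals)[[1]]
intake <- personday_intake(recall, fct_context(fct), db)
dietary_profile(recall, intake)
```

```
Dietary profile: participant A001, 2019-03-12
Meal groups: 3 (breast-milk entries: 0)
  1. 09:00 [mamalishe] maize ugali — 350 g, 392 kcal
  2. 13:20 [home] beef relish with oil — 120 g, 264 kcal
  3. 18:30 [home] maize ugali — 525 g, 588 kcal
Daily totals: 1244.0 kcal, protein 47.9 g (animal 21.6 g), fat 22.4 g, carb 211.2 g
Unresolved foods: 0
```

The first meal (1 medium plate of ugali, 350 g at a *mamalishe* vendor)
supplies 392 kcal; the FAFH energy share is that meal over the daily
total:

```r
fafh_energy_share(intake)
#> [1] 0.3151125
```

and RNI adequacy for a 41-year-old man classifies each nutrient against
the bundled (editable) reference table — e.g. zinc at ratio 1.90 meets
the RNI, calcium at 0.088 does not:

```r
rni_adequacy(intake, list(age_years = 41, sex = "male"))
```

The same functions scale to whole cohorts: `read_recall_tables()` ingests
the two-table export, `validate_recall()` and `daily_report()` drive field
monitoring, `cohort_meal_table()` + `energy_by_meal_order()`,
`fafh_summary()`, `food_frequency_table()` and `timing_histogram()`
produce the analytic summaries, and `generate_recalls()` produces seeded
synthetic cohorts (with optional ground-truth fault injection) for
testing. A thin CLI over these functions is installed at
`inst/cli/recall24.R` with subcommands `simulate`, `ingest`, `validate`,
`compute`, `analyze` and `report`.

## File dialects

* **FCT file** (CSV/TSV, UTF-8): header `code,name,food_group,
  edible_fraction` followed by the 11 nutrient columns named as in
  `nutrient_names()`. Missing nutrient columns default to 0 with a
  warning; duplicate or sentinel codes are errors.
* **Portion database**: `food_code_or_group,utensil,size,grams_per_unit,
  provenance`; food-specific rows beat group defaults.
* **Demographics / meals export**: see `read_recall_tables()`; clock
  times are `"HH:MM"`, a column-mapping argument supports alternative
  headers.
* **Recipe registry and code assignments**: human-editable YAML
  (`save_recipe_registry()`, `save_assignments()`).

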