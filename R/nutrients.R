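#' Bundle the food-composition context for intake computation
#'
#' Collects the primary (and optional secondary) food-composition tables,
#' the code-assignment map for unknown meals, and the recipe registry into
#' one object passed to [personday_intake()].
#'
#' @param primary,secondary `fct_table`s; `secondary` optional.
#' @param assignments Named list from [load_assignments()].
#' @param recipes A [recipe_registry()] or `NULL`.
#' @return Object of class `fct_context`.
#' @export
fct_context <- function(primary, secondary = NULL, assignments = list(),
                        recipes = NULL) {
  stopifnot(inherits(primary, "fct_table"))
  if (!is.null(secondary)) stopifnot(inherits(secondary, "fct_table"))
  if (!is.null(recipes)) stopifnot(inherits(recipes, "recipe_registry"))
  structure(list(primary = primary, secondary = secondary,
                 assignments = assignments, recipes = recipes),
            class = "fct_context")
}

#' Nutrients of a single meal entry
#'
#' Multiplies the resolved item's per-100 g vector by the edible grams
#' consumed: `grams * edible_fraction / 100 * per100g` (per-100 g values
#' refer to edible portion; the edible fraction converts as-served grams).
#' Breast-milk entries are excluded with reason `"breast_milk"` — breast
#' milk is never included in nutrient estimates — and unresolved foods are
#' excluded with reason `"unresolved"`; both carry the zero vector.
#'
#' @param entry One meal entry (one-row tibble or list).
#' @param resolved The `resolved_food` for the entry's code.
#' @param grams Grams consumed as served (>= 0); ignored for excluded
#'   entries.
#' @return List with `grams`, `nutrients` (nutrient vector), `source`,
#'   `excluded` (logical) and `reason` (`NA` when included).
#' @export
meal_nutrients <- function(entry, resolved, grams) {
  if (isTRUE(entry$is_breastmilk[[1]])) {
    return(list(grams = NA_real_, nutrients = nv_zero(),
                source = "breast_milk", excluded = TRUE,
                reason = "breast_milk"))
  }
  stopifnot(inherits(resolved, "resolved_food"))
  if (resolved$source == "unresolved") {
    return(list(grams = NA_real_, nutrients = nv_zero(),
                source = "unresolved", excluded = TRUE,
                reason = "unresolved"))
  }
  grams <- as.numeric(grams)
  if (is.na(grams) || grams < 0) {
    stop("grams must be >= 0 for food entries", call. = FALSE)
  }
  item <- resolved$item
  nut <- grams * item$edible_fraction[1] * item_nutrients(item) / 100
  list(grams = grams, nutrients = nut, source = resolved$source,
       excluded = FALSE, reason = NA_character_)
}

entry_id_of <- function(participant_id, recall_date, entry_index) {
  paste(participant_id, as.character(recall_date), entry_index, sep = "|")
}

#' Per-person-day nutrient intake
#'
#' Resolves every meal entry through [resolve_code()], converts portions to
#' grams with [amount_consumed_g()] (food-specific before food-group
#' precedence), computes per-meal nutrient vectors and sums the non-excluded
#' ones to daily totals. Breast-milk entries contribute timing only;
#' unresolved foods contribute zero and are counted per day rather than
#' failing the whole day. Meal frequencies (including and excluding
#' breast milk) use the meal grouping of [group_meals()].
#'
#' @param recall A `person_day_recall`.
#' @param ctx An [fct_context()].
#' @param db A `portion_db`.
#' @param portion_fallback_g Optional fallback grams per unit for missing
#'   portion mappings (downgrades the error to a warning).
#' @param tolerance_minutes Meal-grouping tolerance.
#' @return Object of class `person_day_intake`: `participant_id`,
#'   `recall_date`, `meals` (one row per entry with grams, exclusion flags
#'   and the eleven nutrient columns), `totals` (nutrient vector),
#'   `meal_frequency_incl_bf`, `meal_frequency_excl_bf`, `n_unresolved`.
#' @export
personday_intake <- function(recall, ctx, db, portion_fallback_g = NULL,
                             tolerance_minutes = 0) {
  stopifnot(inherits(recall, "person_day_recall"),
            inherits(ctx, "fct_context"))
  e <- recall$entries
  n <- nrow(e)
  nut_mat <- matrix(0, nrow = n, ncol = length(nutrient_names()),
                    dimnames = list(NULL, nutrient_names()))
  grams <- rep(NA_real_, n)
  source <- character(n)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)
  audit <- character(n)

  for (i in seq_len(n)) {
    entry <- e[i, , drop = FALSE]
    if (entry$is_breastmilk) {
      mi <- meal_nutrients(entry, NULL, NA)
      audit[i] <- "breast milk: excluded from nutrient estimates"
    } else {
      res <- resolve_code(
        entry$food_code, description = entry$description,
        primary = ctx$primary, secondary = ctx$secondary,
        assignments = ctx$assignments, recipes = ctx$recipes,
        entry_id = entry_id_of(entry$participant_id, entry$recall_date,
                               entry$entry_index))
      audit[i] <- res$audit
      if (res$source == "unresolved") {
        mi <- meal_nutrients(entry, res, NA)
      } else {
        conv <- amount_consumed_g(entry, db,
                                  food_group = res$item$food_group[1],
                                  fallback_g = portion_fallback_g)
        mi <- meal_nutrients(entry, res, conv$grams)
        audit[i] <- paste(audit[i],
                          sprintf("portion %s (%s level)", conv$key,
                                  conv$level), sep = "; ")
      }
    }
    nut_mat[i, ] <- mi$nutrients
    grams[i] <- mi$grams
    source[i] <- mi$source
    excluded[i] <- mi$excluded
    reason[i] <- mi$reason
  }

  meals <- tibble::tibble(
    entry_index = e$entry_index, clock_time = e$clock_time,
    location = e$location, food_code = e$food_code,
    description = e$description, grams = grams, source = source,
    excluded = excluded, reason = reason, audit = audit
  )
  meals <- dplyr::bind_cols(meals, tibble::as_tibble(nut_mat))

  totals <- if (n) {
    keep <- !excluded
    stats::setNames(colSums(nut_mat[keep, , drop = FALSE]), nutrient_names())
  } else {
    nv_zero()
  }

  structure(
    list(participant_id = recall$demographics$participant_id,
         recall_date = recall$demographics$recall_date,
         meals = meals, totals = totals,
         meal_frequency_incl_bf = meal_frequency(recall, TRUE,
                                                 tolerance_minutes),
         meal_frequency_excl_bf = meal_frequency(recall, FALSE,
                                                 tolerance_minutes),
         n_unresolved = sum(reason %in% "unresolved")),
    class = "person_day_intake"
  )
}

#' @export
print.person_day_intake <- function(x, ...) {
  cat(sprintf(
    "<person_day_intake %s @ %s: %.0f kcal over %d meal group(s); %d unresolved>\n",
    x$participant_id, as.character(x$recall_date),
    x$totals[["energy_kcal"]], x$meal_frequency_incl_bf, x$n_unresolved))
  invisible(x)
}

#' Flatten person-day intakes to a table
#'
#' @param intakes List of `person_day_intake`.
#' @return Tibble with one row per person-day: key columns, meal
#'   frequencies, unresolved count and the eleven nutrient totals.
#' @export
intake_table <- function(intakes) {
  dplyr::bind_rows(lapply(intakes, function(it) {
    dplyr::bind_cols(
      tibble::tibble(participant_id = it$participant_id,
                     recall_date = it$recall_date,
                     meal_frequency_incl_bf = it$meal_frequency_incl_bf,
                     meal_frequency_excl_bf = it$meal_frequency_excl_bf,
                     n_unresolved = it$n_unresolved),
      tibble::as_tibble(as.list(it$totals)))
  }))
}

#' Bundled recommended-nutrient-intake (RNI) defaults
#'
#' Editable reference table mapping (nutrient, age band in months, sex,
#' bioavailability tier) to a daily RNI. Only the breast-milk-adjusted
#' folate value for 9--11 months (27.6 ug/d) is a fixed constant of the
#' package; the remaining rows are shipped as convenient defaults in the
#' magnitude range of the UN RNI references and are intended to be replaced
#' by the user's authoritative table (see [rni_adequacy()]'s `rni`
#' argument). Iron rows assume 10% bioavailability and zinc rows moderate
#' bioavailability.
#'
#' @return Tibble with columns `nutrient`, `age_min_mo`, `age_max_mo`,
#'   `sex` (`"any"`, `"male"`, `"female"`), `bioavailability`,
#'   `breastmilk_adjusted`, `rni`, `note`.
#' @export
rni_table_default <- function() {
  tb <- tibble::tribble(
    ~nutrient, ~age_min_mo, ~age_max_mo, ~sex, ~bioavailability,
    ~breastmilk_adjusted, ~rni, ~note,
    "calcium_mg", 6, 11, "any", "", FALSE, 400, "editable default",
    "calcium_mg", 12, 35, "any", "", FALSE, 500, "editable default",
    "calcium_mg", 216, 1188, "any", "", FALSE, 1000, "editable default",
    "iron_mg", 6, 11, "any", "10%", FALSE, 9.3, "editable default",
    "iron_mg", 12, 35, "any", "10%", FALSE, 5.8, "editable default",
    "iron_mg", 216, 1188, "male", "10%", FALSE, 13.7, "editable default",
    "iron_mg", 216, 1188, "female", "10%", FALSE, 29.4, "editable default",
    "zinc_mg", 6, 11, "any", "moderate", FALSE, 4.1, "editable default",
    "zinc_mg", 12, 35, "any", "moderate", FALSE, 4.1, "editable default",
    "zinc_mg", 216, 1188, "male", "moderate", FALSE, 7.0, "editable default",
    "zinc_mg", 216, 1188, "female", "moderate", FALSE, 4.9, "editable default",
    "vitA_ug_RE", 6, 11, "any", "", FALSE, 400, "editable default",
    "vitA_ug_RE", 12, 35, "any", "", FALSE, 400, "editable default",
    "vitA_ug_RE", 216, 1188, "male", "", FALSE, 600, "editable default",
    "vitA_ug_RE", 216, 1188, "female", "", FALSE, 500, "editable default",
    "folate_ug", 6, 8, "any", "", FALSE, 80, "editable default",
    "folate_ug", 9, 11, "any", "", FALSE, 80, "editable default",
    "folate_ug", 9, 11, "any", "", TRUE, 27.6,
    "breast-milk-adjusted constant",
    "folate_ug", 12, 35, "any", "", FALSE, 150, "editable default",
    "folate_ug", 216, 1188, "any", "", FALSE, 400, "editable default"
  )
  stopifnot(all(tb$rni > 0))
  tb
}

#' RNI adequacy of a person-day intake
#'
#' For each nutrient with a matching RNI row (age band containing the
#' profile age, sex equal or `"any"`, breast-milk-adjusted rows preferred
#' for breastfed profiles), reports the intake-to-RNI ratio and whether the
#' intake meets the RNI (`ratio >= 1`). Nutrients with no matching row are
#' marked not evaluable.
#'
#' @param intake A `person_day_intake` or a nutrient vector of totals.
#' @param profile List with `age_months` (or `age_years`), `sex`
#'   (`"male"`/`"female"`), and optional `breastfed` (logical).
#' @param rni RNI table as in [rni_table_default()].
#' @return Tibble with `nutrient`, `intake`, `rni`, `ratio`, `meets`,
#'   `evaluable`.
#' @export
rni_adequacy <- function(intake, profile, rni = rni_table_default()) {
  totals <- if (inherits(intake, "person_day_intake")) intake$totals
            else validate_nutrient_vector(intake)
  age_mo <- profile$age_months %||% (profile$age_years * 12)
  sex <- profile$sex %||% "any"
  breastfed <- isTRUE(profile$breastfed)
  rows <- lapply(nutrient_names(), function(nm) {
    cand <- rni[rni$nutrient == nm &
                  rni$age_min_mo <= age_mo & age_mo <= rni$age_max_mo &
                  (rni$sex == "any" | rni$sex == sex), , drop = FALSE]
    if (breastfed && any(cand$breastmilk_adjusted)) {
      cand <- cand[cand$breastmilk_adjusted, , drop = FALSE]
    } else {
      cand <- cand[!cand$breastmilk_adjusted, , drop = FALSE]
    }
    if (nrow(cand) == 0L) {
      return(tibble::tibble(nutrient = nm, intake = totals[[nm]],
                            rni = NA_real_, ratio = NA_real_, meets = NA,
                            evaluable = FALSE))
    }
    r <- totals[[nm]] / cand$rni[1]
    tibble::tibble(nutrient = nm, intake = totals[[nm]], rni = cand$rni[1],
                   ratio = r, meets = r >= 1, evaluable = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Acceptable energy-intake ranges for breastfed children
#'
#' Default table of acceptable daily energy-intake ranges from
#' complementary foods for breastfed children: 100--600 kcal at 6--8
#' months, 200--750 kcal at 9--11 months, and 500--1100 kcal at 12--23
#' months. Ranges for non-breastfed children are not shipped and must be
#' supplied by the user.
#'
#' @return Tibble with `age_min_mo`, `age_max_mo`, `breastfed`,
#'   `lower_kcal`, `upper_kcal`.
#' @export
energy_range_table_default <- function() {
  tb <- tibble::tibble(
    age_min_mo = c(6, 9, 12), age_max_mo = c(8, 11, 23),
    breastfed = TRUE,
    lower_kcal = c(100, 200, 500), upper_kcal = c(600, 750, 1100))
  stopifnot(all(tb$lower_kcal < tb$upper_kcal))
  tb
}

#' Classify a child's energy intake against the acceptable range
#'
#' Classification is by the closed interval `[lower, upper]` (boundary
#' values are `"within"`); the matched bounds are returned for audit. An
#' age/breastfed combination not covered by the table is `"not_evaluable"`.
#'
#' @param energy_kcal Daily energy intake in kcal.
#' @param age_months Child age in months.
#' @param breastfed Logical.
#' @param table Range table as in [energy_range_table_default()].
#' @return List with `classification` (`"below"`, `"within"`, `"above"` or
#'   `"not_evaluable"`), `lower_kcal`, `upper_kcal`.
#' @export
energy_range_check <- function(energy_kcal, age_months, breastfed,
                               table = energy_range_table_default()) {
  hit <- table[table$age_min_mo <= age_months &
                 age_months <= table$age_max_mo &
                 table$breastfed == breastfed, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(list(classification = "not_evaluable", lower_kcal = NA_real_,
                upper_kcal = NA_real_))
  }
  lo <- hit$lower_kcal[1]
  hi <- hit$upper_kcal[1]
  cls <- if (energy_kcal < lo) "below"
         else if (energy_kcal > hi) "above"
         else "within"
  list(classification = cls, lower_kcal = lo, upper_kcal = hi)
}
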