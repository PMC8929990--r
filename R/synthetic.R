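#' Simulation configuration for synthetic cohorts
#'
#' Parameters of the seeded generator that emulates the two-table recall
#' export of two study populations: an adult peri-urban cohort (mostly
#' female, median 3--4 meals a day, men eating away from home far more
#' often than women) and a rural child cohort under 25 months with
#' age-graded breastfeeding. Defaults mirror the printed medians of the
#' motivating field tables (breastfeeding frequency medians 7/5/4/0 by age
#' band; meal frequency including breastfeeding 9/9/8/6) as plausibility
#' anchors; they are defaults, not estimates.
#'
#' Meal-time modes default to 09:00 / 13:25 / 18:15. The evening mode is
#' set so that typical midday-to-evening gaps stay inside the
#' quality-control plausibility window for consecutive-meal gaps; a
#' gap-compression pass guarantees clean data never exceed
#' `max_gap_minutes`, so injected TIME_GAP faults are the only source of
#' long gaps.
#'
#' @param n_adults,n_children Cohort sizes.
#' @param adult_female_prop,child_female_prop Sex ratios.
#' @param adult_meal_modes,adult_meal_sds Clock-time mixture (minutes of
#'   day) for the three main adult meals.
#' @param snack_mode,snack_sd Timing of the optional fourth meal.
#' @param extra_meal_prob Probability of the fourth meal.
#' @param items_per_meal_probs Probabilities of 1, 2 or 3 items per meal.
#' @param portion_choices,child_portion_choices Portion-count options.
#' @param fafh_any_prob Named probability (by sex) that an adult eats away
#'   from home at all.
#' @param fafh_energy_share Named target (by sex) away-from-home share of
#'   daily energy for adults who eat away.
#' @param unknown_rate Fraction of food entries recorded under the unknown
#'   sentinel code 9999 with a post-hoc assignment.
#' @param fault_rates Named per-recall injection rates for
#'   `BF_MISMATCH`, `TWO_MORNINGS`, `IMPLAUSIBLE_PORTION`, `TIME_GAP`
#'   (all 0 by default).
#' @param max_gap_minutes Gap ceiling enforced on clean data.
#' @param dates Candidate recall dates (one week by default, so weekday
#'   strata are populated).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_adults = 100, n_children = 100,
                       adult_female_prop = 0.753,
                       child_female_prop = 0.497,
                       adult_meal_modes = c(540, 805, 1095),
                       adult_meal_sds = c(40, 45, 35),
                       snack_mode = 975, snack_sd = 40,
                       extra_meal_prob = 0.3,
                       items_per_meal_probs = c(0.5, 0.35, 0.15),
                       portion_choices = c(0.5, 1, 1.5, 2),
                       child_portion_choices = c(0.25, 0.5, 1),
                       fafh_any_prob = c(male = 0.37, female = 0.076),
                       fafh_energy_share = c(male = 0.5, female = 0.1),
                       unknown_rate = 0.03,
                       fault_rates = c(BF_MISMATCH = 0, TWO_MORNINGS = 0,
                                       IMPLAUSIBLE_PORTION = 0,
                                       TIME_GAP = 0),
                       max_gap_minutes = 360,
                       dates = as.Date("2019-03-11") + 0:6) {
  stopifnot(n_adults >= 0, n_children >= 0,
            adult_female_prop >= 0, adult_female_prop <= 1,
            length(adult_meal_modes) == 3, length(adult_meal_sds) == 3,
            all(items_per_meal_probs >= 0),
            abs(sum(items_per_meal_probs) - 1) < 1e-8,
            all(fafh_any_prob >= 0 & fafh_any_prob <= 1),
            all(fafh_energy_share >= 0 & fafh_energy_share < 1),
            unknown_rate >= 0, unknown_rate <= 1,
            all(fault_rates >= 0 & fault_rates <= 1),
            max_gap_minutes > 0)
  bands <- tibble::tibble(
    band = c("0-5", "6-12", "13-18", "19-24"),
    age_min = c(0, 6, 13, 19), age_max = c(5, 12, 18, 24),
    prob = c(83, 360, 262, 140) / 845,
    breastfed_prob = c(1, 0.975, 0.779, 0.386),
    bf_freq_median = c(7, 5, 4, 0),
    food_meals = c(2, 3, 4, 5))
  structure(
    list(n_adults = n_adults, n_children = n_children,
         adult_female_prop = adult_female_prop,
         child_female_prop = child_female_prop,
         adult_meal_modes = adult_meal_modes,
         adult_meal_sds = adult_meal_sds,
         snack_mode = snack_mode, snack_sd = snack_sd,
         extra_meal_prob = extra_meal_prob,
         items_per_meal_probs = items_per_meal_probs,
         portion_choices = portion_choices,
         child_portion_choices = child_portion_choices,
         fafh_any_prob = fafh_any_prob,
         fafh_energy_share = fafh_energy_share,
         unknown_rate = unknown_rate, fault_rates = fault_rates,
         max_gap_minutes = max_gap_minutes, dates = dates,
         child_bands = bands),
    class = "sim_config")
}

sim_food_groups <- function() {
  list(
    cereals = list(energy = c(90, 370), protein = c(2, 12),
                   fat = c(0.5, 6), carb = c(18, 80), fiber = c(1, 10),
                   ca = c(5, 50), fe = c(0.5, 4), zn = c(0.5, 3),
                   va = c(0, 10), fol = c(10, 60), animal = FALSE,
                   ef = c(1, 1)),
    roots_tubers = list(energy = c(75, 160), protein = c(1, 3),
                        fat = c(0.1, 0.5), carb = c(17, 38),
                        fiber = c(1, 4), ca = c(10, 40), fe = c(0.3, 1.5),
                        zn = c(0.2, 0.8), va = c(0, 20), fol = c(10, 30),
                        animal = FALSE, ef = c(0.8, 1)),
    legumes = list(energy = c(100, 350), protein = c(7, 24),
                   fat = c(0.5, 2.5), carb = c(15, 60), fiber = c(4, 16),
                   ca = c(30, 120), fe = c(2, 7), zn = c(1, 4),
                   va = c(0, 5), fol = c(80, 300), animal = FALSE,
                   ef = c(1, 1)),
    vegetables = list(energy = c(20, 60), protein = c(1, 4),
                      fat = c(0.1, 1), carb = c(3, 10), fiber = c(1, 4),
                      ca = c(30, 250), fe = c(0.5, 4), zn = c(0.2, 1),
                      va = c(50, 600), fol = c(20, 150), animal = FALSE,
                      ef = c(0.7, 1)),
    fruits = list(energy = c(30, 100), protein = c(0.3, 1.5),
                  fat = c(0.1, 0.5), carb = c(8, 25), fiber = c(1, 5),
                  ca = c(5, 30), fe = c(0.1, 0.8), zn = c(0.05, 0.3),
                  va = c(5, 120), fol = c(5, 40), animal = FALSE,
                  ef = c(0.55, 0.95)),
    meat = list(energy = c(120, 280), protein = c(15, 28), fat = c(3, 22),
                carb = c(0, 2), fiber = c(0, 0), ca = c(5, 25),
                fe = c(1, 4), zn = c(2, 7), va = c(0, 30), fol = c(2, 15),
                animal = TRUE, ef = c(0.8, 1)),
    fish = list(energy = c(90, 220), protein = c(15, 30), fat = c(1, 12),
                carb = c(0, 2), fiber = c(0, 0), ca = c(20, 400),
                fe = c(0.5, 4), zn = c(0.5, 3), va = c(5, 60),
                fol = c(5, 20), animal = TRUE, ef = c(0.7, 1)),
    dairy = list(energy = c(45, 120), protein = c(3, 7), fat = c(2, 8),
                 carb = c(4, 7), fiber = c(0, 0), ca = c(90, 180),
                 fe = c(0, 0.2), zn = c(0.3, 0.7), va = c(20, 70),
                 fol = c(3, 10), animal = TRUE, ef = c(1, 1)),
    fats_oils = list(energy = c(700, 900), protein = c(0, 0.5),
                     fat = c(78, 100), carb = c(0, 1), fiber = c(0, 0),
                     ca = c(0, 5), fe = c(0, 0.2), zn = c(0, 0.1),
                     va = c(0, 600), fol = c(0, 2), animal = FALSE,
                     ef = c(1, 1)),
    beverages = list(energy = c(1, 50), protein = c(0, 1),
                     fat = c(0, 0.5), carb = c(0, 12), fiber = c(0, 0.5),
                     ca = c(0, 15), fe = c(0, 0.3), zn = c(0, 0.2),
                     va = c(0, 5), fol = c(0, 10), animal = FALSE,
                     ef = c(1, 1))
  )
}

sim_food_row <- function(code, group, spec, i) {
  r <- function(rng) stats::runif(1, rng[1], rng[2])
  protein <- r(spec$protein)
  animal <- if (spec$animal) protein * stats::runif(1, 0.8, 1) else 0
  tibble::tibble(
    code = code, name = sprintf("%s item %d", group, i), food_group = group,
    edible_fraction = round(r(spec$ef), 3),
    energy_kcal = round(r(spec$energy), 1),
    protein_g = round(protein, 2),
    animal_protein_g = round(animal, 2),
    fat_g = round(r(spec$fat), 2), carb_g = round(r(spec$carb), 2),
    fiber = round(r(spec$fiber), 2), calcium_mg = round(r(spec$ca), 1),
    iron_mg = round(r(spec$fe), 2), zinc_mg = round(r(spec$zn), 2),
    vitA_ug_RE = round(r(spec$va), 1), folate_ug = round(r(spec$fol), 1))
}

#' Generate a mock food-composition and portion-size context
#'
#' Builds a primary food-composition table over ten food groups (four foods
#' each), a small secondary table of foods reachable only through unknown
#' -code assignments, a portion-size database with a group-level default
#' for every (group, utensil, size) key plus a few food-specific overrides,
#' and the seven-utensil registry. Every generated food is portion-
#' resolvable by construction; nutrient vectors are nonnegative with
#' animal-source protein bounded by protein; edible fractions lie in
#' (0, 1].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces identical tables.
#' @return List with `primary`, `secondary` (`fct_table`s), `portion_db`,
#'   `utensils`.
#' @export
generate_fct <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  groups <- sim_food_groups()
  rows <- list()
  k <- 0
  for (g in names(groups)) {
    for (i in 1:4) {
      k <- k + 1
      rows[[k]] <- sim_food_row(sprintf("T%03d", k), g, groups[[g]], i)
    }
  }
  primary <- fct_table(dplyr::bind_rows(rows), "primary")

  sec_groups <- c("fish", "fruits", "cereals", "meat", "vegetables",
                  "legumes")
  sec_rows <- lapply(seq_along(sec_groups), function(i) {
    sim_food_row(sprintf("K%03d", i), sec_groups[i],
                 groups[[sec_groups[i]]], i + 100)
  })
  secondary <- fct_table(dplyr::bind_rows(sec_rows), "secondary")

  utensils <- utensil_registry()
  base_g <- c(bowl = 300, cup = 240, tumbler = 250, plate = 350,
              tablespoon = 15, teaspoon = 5, saucer = 150)
  size_mult <- c(small = 0.6, medium = 1, large = 1.5)
  pe <- list()
  for (g in names(groups)) {
    dens <- stats::runif(1, 0.8, 1.2)
    for (u in names(base_g)) {
      for (s in names(size_mult)) {
        pe[[length(pe) + 1]] <- tibble::tibble(
          food_code_or_group = g, utensil = u, size = s,
          grams_per_unit = round(base_g[[u]] * size_mult[[s]] * dens, 1),
          provenance = "group default (synthetic)")
      }
    }
  }
  # Food-specific overrides so the precedence rule is exercised.
  for (code in c("T001", "T005", "T009")) {
    pe[[length(pe) + 1]] <- tibble::tibble(
      food_code_or_group = code, utensil = "bowl", size = "medium",
      grams_per_unit = round(stats::runif(1, 180, 380), 1),
      provenance = "food-specific (synthetic)")
  }
  db <- portion_db(dplyr::bind_rows(pe))
  list(primary = primary, secondary = secondary, portion_db = db,
       utensils = utensils)
}

# Grams-per-unit lookup used inside the generator; mirrors the precedence
# of amount_consumed_g (food-specific key on the recorded code, then the
# resolved food's group default).
sim_gpu <- function(db, code, group, utensil, size) {
  e <- db$entries
  hit <- which(e$food_code_or_group == code & e$utensil == utensil &
                 e$size == size)
  if (!length(hit)) {
    hit <- which(e$food_code_or_group == group & e$utensil == utensil &
                   e$size == size)
  }
  e$grams_per_unit[hit[1]]
}

# Shift later times down so no consecutive gap exceeds max_gap; returns a
# mapping applied to all entry times (breast-milk included).
compress_gaps <- function(times, max_gap) {
  u <- sort(unique(times))
  if (length(u) < 2) return(times)
  v <- u
  for (j in 2:length(u)) {
    gap <- v[j] - v[j - 1]
    if (gap > max_gap) v[j:length(v)] <- v[j:length(v)] - (gap - max_gap)
  }
  v[match(times, u)]
}

strictly_increasing <- function(t, step = 10, cap = 1435) {
  t <- sort(round(t))
  for (j in seq_along(t)[-1]) t[j] <- max(t[j], t[j - 1] + step)
  pmin(pmax(t, 240), cap)
}

sim_meal_entries <- function(pid, date, times, foods_tbl, db, cfg,
                             utensil_pool, size_pool, portion_pool,
                             n_items_probs) {
  rows <- list()
  for (ti in seq_along(times)) {
    n_items <- sample(seq_along(n_items_probs), 1, prob = n_items_probs)
    pick <- foods_tbl[sample(nrow(foods_tbl), n_items), , drop = FALSE]
    for (j in seq_len(n_items)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = pid, recall_date = date, entry_index = NA_integer_,
        clock_time = times[ti], meal_slot = ti, location = "home",
        food_code = pick$code[j], description = pick$name[j],
        ingredients = "", utensil = sample(utensil_pool, 1),
        utensil_size = sample(size_pool, 1),
        portion_count = sample(portion_pool, 1), is_breastmilk = FALSE,
        comments = "")
    }
  }
  dplyr::bind_rows(rows)
}

sim_entry_energy <- function(entries, fct, db) {
  vapply(seq_len(nrow(entries)), function(i) {
    if (entries$is_breastmilk[i]) return(0)
    code <- entries$food_code[i]
    item <- fct_lookup(fct$primary, code)
    if (is.null(item)) item <- fct_lookup(fct$secondary, code)
    if (is.null(item)) {  # sentinel: resolve via true_code column
      item <- fct_lookup(fct$primary, entries$true_code[i])
      if (is.null(item)) item <- fct_lookup(fct$secondary,
                                            entries$true_code[i])
    }
    gpu <- sim_gpu(db, code, item$food_group[1], entries$utensil[i],
                   entries$utensil_size[i])
    grams <- entries$portion_count[i] * gpu
    grams * item$edible_fraction[1] * item$energy_kcal[1] / 100
  }, numeric(1))
}

#' Generate a synthetic two-table recall export
#'
#' Emulates the field export: a demographics table (one row per participant
#' per day) and a meals table (multiple rows per participant per day), for
#' an adult cohort and a child cohort, together with the unknown-code
#' assignment map and, when fault rates are configured, the ground-truth
#' fault list. Without fault injection, [validate_recall()] returns no
#' findings on any generated recall and every child's breast-milk entry
#' count equals the declared frequency. Adults who eat away from home have
#' their away-meal portions rescaled so the away-from-home energy share
#' matches the configured per-sex target.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param fct Output of [generate_fct()]; generated from the same seed
#'   when `NULL`.
#' @return List with `demographics`, `meals` (tibbles in the export
#'   schemas), `assignments` (named list), `faults` (tibble with
#'   `participant_id`, `recall_date`, `rule_id`), `fct` and `context`
#'   (an [fct_context()] ready for [personday_intake()]).
#' @export
generate_recalls <- function(config = sim_config(), seed = 1, fct = NULL) {
  if (is.null(fct)) fct <- generate_fct(config, seed)
  set.seed(seed + 1L)
  gap_target <- config$max_gap_minutes - 20

  persons <- list()
  assignments <- list()

  away_levels <- setdiff(location_levels(), c("home", "other"))
  away_weights <- list(
    male = c(work = 30, friend_house = 6, roadside_vendor = 26,
             mamalishe = 55, restaurant = 57, hotel = 11),
    female = c(work = 35, friend_house = 8, roadside_vendor = 18,
               mamalishe = 10, restaurant = 34, hotel = 6))

  adult_codes <- fct$primary$items
  child_groups <- c("cereals", "dairy", "fruits", "roots_tubers", "fish")
  child_codes <- adult_codes[adult_codes$food_group %in% child_groups, ,
                             drop = FALSE]

  for (i in seq_len(config$n_adults)) {
    pid <- sprintf("A%04d", i)
    sex <- sample(c("female", "male"), 1,
                  prob = c(config$adult_female_prop,
                           1 - config$adult_female_prop))
    date <- config$dates[sample(length(config$dates), 1)]
    times <- stats::rnorm(3, config$adult_meal_modes, config$adult_meal_sds)
    if (stats::runif(1) < config$extra_meal_prob) {
      times <- c(times, stats::rnorm(1, config$snack_mode, config$snack_sd))
    }
    times <- strictly_increasing(times)
    times <- compress_gaps(times, gap_target)
    e <- sim_meal_entries(pid, date, times, adult_codes, fct$portion_db,
                          config, c("bowl", "cup", "plate", "tumbler"),
                          c("small", "medium", "large"),
                          config$portion_choices,
                          config$items_per_meal_probs)
    e$true_code <- e$food_code

    # Unknown sentinel usage with post-hoc assignment.
    for (r in which(stats::runif(nrow(e)) < config$unknown_rate)) {
      if (stats::runif(1) < 0.25) {
        srow <- fct$secondary$items[sample(nrow(fct$secondary$items), 1), ]
        e$true_code[r] <- srow$code
        e$description[r] <- srow$name
      }
      e$food_code[r] <- UNKNOWN_CODE
    }

    # Away-from-home selection and energy-share targeting.
    if (stats::runif(1) < config$fafh_any_prob[[sex]] &&
        length(times) >= 2) {
      n_away_slots <- if (sex == "male") min(2, length(times) - 1) else 1
      away_slots <- seq_len(n_away_slots)
      energy <- sim_entry_energy(e, fct, fct$portion_db)
      is_away <- e$meal_slot %in% away_slots
      e_away <- sum(energy[is_away])
      e_home <- sum(energy[!is_away])
      t_share <- config$fafh_energy_share[[sex]]
      if (e_away > 0 && e_home > 0 && t_share > 0) {
        f <- t_share * e_home / ((1 - t_share) * e_away)
        f <- min(max(f, 0.05), 2.5)
        e$portion_count[is_away] <- pmax(
          round(e$portion_count[is_away] * f, 3), 0.05)
      }
      w <- away_weights[[sex]]
      for (slot in away_slots) {
        loc <- sample(names(w), 1, prob = w)
        e$location[e$meal_slot == slot] <- loc
      }
    }
    e <- e[order(e$clock_time), , drop = FALSE]
    e$entry_index <- seq_len(nrow(e))
    demog <- tibble::tibble(
      participant_id = pid, recall_date = date, cohort = "adults",
      age_value = round(stats::runif(1, 20, 60)), age_unit = "years",
      sex = sex,
      day_character = sample(c("typical", "fasting", "holiday_special"), 1,
                             prob = c(0.97, 0.016, 0.014)),
      supplement_use = stats::runif(1) < 0.01,
      declared_bf_frequency = 0L)
    persons[[length(persons) + 1]] <- list(demog = demog, entries = e)
  }

  bands <- config$child_bands
  for (i in seq_len(config$n_children)) {
    pid <- sprintf("C%04d", i)
    b <- bands[sample(nrow(bands), 1, prob = bands$prob), ]
    age_mo <- sample(b$age_min:b$age_max, 1)
    sex <- sample(c("female", "male"), 1,
                  prob = c(config$child_female_prop,
                           1 - config$child_female_prop))
    date <- config$dates[sample(length(config$dates), 1)]
    breastfed <- stats::runif(1) < b$breastfed_prob
    bf_n <- if (breastfed) {
      max(1L, as.integer(round(stats::rnorm(1, b$bf_freq_median, 1.2))))
    } else 0L
    food_n <- max(1L, b$food_meals + sample(-1:1, 1))
    food_times <- if (food_n == 1) 780 else {
      seq(420, 1140, length.out = food_n) + stats::rnorm(food_n, 0, 25)
    }
    food_times <- strictly_increasing(food_times)
    e <- sim_meal_entries(pid, date, food_times, child_codes,
                          fct$portion_db, config,
                          c("cup", "bowl", "tablespoon"),
                          c("small", "medium"),
                          config$child_portion_choices,
                          c(0.6, 0.4))
    e$location <- ifelse(stats::runif(nrow(e)) < 0.95, "home", "other")
    e$true_code <- e$food_code
    for (r in which(stats::runif(nrow(e)) < config$unknown_rate)) {
      if (stats::runif(1) < 0.25) {
        srow <- fct$secondary$items[sample(nrow(fct$secondary$items), 1), ]
        e$true_code[r] <- srow$code
        e$description[r] <- srow$name
      }
      e$food_code[r] <- UNKNOWN_CODE
    }
    if (bf_n > 0) {
      bf_times <- sort(round(stats::runif(bf_n, 330, 1290)))
      bf <- tibble::tibble(
        participant_id = pid, recall_date = date, entry_index = NA_integer_,
        clock_time = as.integer(bf_times), meal_slot = NA_integer_,
        location = "home", food_code = "", description = "breast milk",
        ingredients = "", utensil = "", utensil_size = "",
        portion_count = NA_real_, is_breastmilk = TRUE, comments = "",
        true_code = "")
      e <- dplyr::bind_rows(e, bf)
    }
    e$clock_time <- compress_gaps(e$clock_time, gap_target)
    e <- e[order(e$clock_time, e$is_breastmilk), , drop = FALSE]
    e$entry_index <- seq_len(nrow(e))
    demog <- tibble::tibble(
      participant_id = pid, recall_date = date, cohort = "children",
      age_value = age_mo, age_unit = "months", sex = sex,
      day_character = sample(c("typical", "holiday_special"), 1,
                             prob = c(0.969, 0.031)),
      supplement_use = FALSE,
      declared_bf_frequency = bf_n)
    persons[[length(persons) + 1]] <- list(demog = demog, entries = e)
  }

  injected <- inject_faults(persons, config, fct)
  persons <- injected$persons

  # Assignment map keyed by final entry ids (indices are final after the
  # chronological sort; unknown rows are identified by their sentinel code).
  for (p in persons) {
    e <- p$entries
    for (r in which(e$food_code == UNKNOWN_CODE)) {
      eid <- entry_id_of(e$participant_id[r], e$recall_date[r],
                         e$entry_index[r])
      assignments[[eid]] <- e$true_code[r]
    }
  }

  demographics <- dplyr::bind_rows(lapply(persons, `[[`, "demog"))
  meals <- dplyr::bind_rows(lapply(persons, function(p) {
    p$entries[, meal_columns()]
  }))
  list(demographics = demographics, meals = meals,
       assignments = assignments, faults = injected$faults, fct = fct,
       context = fct_context(fct$primary, fct$secondary,
                             assignments = assignments))
}

inject_faults <- function(persons, config, fct) {
  n <- length(persons)
  rates <- config$fault_rates
  faults <- list()
  counts <- vapply(qc_rule_ids()[1:4], function(r) {
    as.integer(round((rates[[r]] %||% 0) * n))
  }, integer(1))
  total <- sum(counts)
  if (total == 0) {
    return(list(persons = persons,
                faults = tibble::tibble(participant_id = character(),
                                        recall_date = as.Date(character()),
                                        rule_id = character())))
  }
  if (total > n) stop("fault rates exceed cohort size", call. = FALSE)
  # Disjoint targets so the finding multiset equals the injected multiset.
  eligible_gap <- which(vapply(persons, function(p) {
    length(unique(p$entries$clock_time)) >= 2
  }, logical(1)))
  targets <- sample(n, total)
  idx <- split(targets, rep(names(counts), counts))

  for (i in idx[["BF_MISMATCH"]] %||% integer()) {
    persons[[i]]$demog$declared_bf_frequency <-
      persons[[i]]$demog$declared_bf_frequency + 1L
    faults[[length(faults) + 1]] <-
      c(persons[[i]]$demog$participant_id,
        as.character(persons[[i]]$demog$recall_date), "BF_MISMATCH")
  }

  for (i in idx[["TWO_MORNINGS"]] %||% integer()) {
    e <- persons[[i]]$entries
    first_food <- fct$primary$items[1, ]
    if (min(e$clock_time) >= 555) {
      # ensure a pre-decrease morning time exists
      extra <- e[1, , drop = FALSE]
      extra$clock_time <- 555L
      extra$is_breastmilk <- FALSE
      extra$food_code <- first_food$code
      extra$true_code <- first_food$code
      extra$description <- first_food$name
      extra$utensil <- "cup"
      extra$utensil_size <- "small"
      extra$portion_count <- 0.5
      extra$location <- "home"
      e <- dplyr::bind_rows(extra, e)
      e <- e[order(e$clock_time, e$is_breastmilk), , drop = FALSE]
    }
    tail_row <- e[nrow(e), , drop = FALSE]
    tail_row$clock_time <- if (420L %in% e$clock_time) 425L else 420L
    tail_row$is_breastmilk <- FALSE
    tail_row$food_code <- first_food$code
    tail_row$true_code <- first_food$code
    tail_row$description <- first_food$name
    tail_row$utensil <- "cup"
    tail_row$utensil_size <- "small"
    tail_row$portion_count <- 0.5
    tail_row$location <- "home"
    e <- dplyr::bind_rows(e, tail_row)   # second morning, recorded last
    e$entry_index <- seq_len(nrow(e))
    persons[[i]]$entries <- e
    faults[[length(faults) + 1]] <-
      c(persons[[i]]$demog$participant_id,
        as.character(persons[[i]]$demog$recall_date), "TWO_MORNINGS")
  }

  for (i in idx[["IMPLAUSIBLE_PORTION"]] %||% integer()) {
    e <- persons[[i]]$entries
    cand <- which(!e$is_breastmilk & e$food_code != UNKNOWN_CODE)
    r <- cand[1]
    e$utensil[r] <- "plate"
    e$utensil_size[r] <- "large"
    e$portion_count[r] <- 50
    persons[[i]]$entries <- e
    faults[[length(faults) + 1]] <-
      c(persons[[i]]$demog$participant_id,
        as.character(persons[[i]]$demog$recall_date),
        "IMPLAUSIBLE_PORTION")
  }

  for (i in idx[["TIME_GAP"]] %||% integer()) {
    if (!length(unique(persons[[i]]$entries$clock_time)) >= 2) {
      # swap for an eligible person not already targeted
      spare <- setdiff(eligible_gap, targets)
      i <- spare[1]
    }
    e <- persons[[i]]$entries
    u <- sort(unique(e$clock_time))
    v <- u
    v[2] <- v[1] + config$max_gap_minutes + 60
    if (length(u) > 2) {
      v[3:length(v)] <- v[2] + cumsum(rep(45, length(v) - 2))
    }
    v <- pmin(v, 1435)
    e$clock_time <- v[match(e$clock_time, u)]
    e <- e[order(e$clock_time, e$is_breastmilk), , drop = FALSE]
    e$entry_index <- seq_len(nrow(e))
    persons[[i]]$entries <- e
    faults[[length(faults) + 1]] <-
      c(persons[[i]]$demog$participant_id,
        as.character(persons[[i]]$demog$recall_date), "TIME_GAP")
  }

  ft <- tibble::tibble(
    participant_id = vapply(faults, `[[`, character(1), 1),
    recall_date = as.Date(vapply(faults, `[[`, character(1), 2)),
    rule_id = vapply(faults, `[[`, character(1), 3))
  list(persons = persons, faults = ft)
}

#' Write a generated cohort to disk
#'
#' Emits the same file dialects the ingest module reads: `demographics.csv`,
#' `meals.csv`, `fct_primary.csv`, `fct_secondary.csv`, `portion_db.csv`
#' and `assignments.yaml` under `dir`.
#'
#' @param gen Output of [generate_recalls()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(gen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    meals = file.path(dir, "meals.csv"),
    fct_primary = file.path(dir, "fct_primary.csv"),
    fct_secondary = file.path(dir, "fct_secondary.csv"),
    portion_db = file.path(dir, "portion_db.csv"),
    assignments = file.path(dir, "assignments.yaml"))
  recalls <- assemble_recalls(gen$demographics, gen$meals)
  write_normalized(recalls, paths[["demographics"]], paths[["meals"]])
  write_fct(gen$fct$primary, paths[["fct_primary"]])
  write_fct(gen$fct$secondary, paths[["fct_secondary"]])
  write_portion_db(gen$fct$portion_db, paths[["portion_db"]])
  save_assignments(gen$assignments, paths[["assignments"]])
  invisible(paths)
}
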