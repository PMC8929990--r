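test_that("entries at the same time form one meal group", {
  r <- mk_recall(mk_demog(),
                 mk_entry(idx = 1, time = 540, code = "101"),
                 mk_entry(idx = 2, time = 540, code = "102"),
                 mk_entry(idx = 3, time = 540, code = "104"))
  g <- group_meals(r)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_entries, 3)
  expect_equal(sort(unlist(g$entry_indices)), 1:3)
})

test_that("distinct times form ordered groups and empty recalls give empty tables", {
  r <- mk_recall(mk_demog(),
                 mk_entry(idx = 1, time = 780),
                 mk_entry(idx = 2, time = 540))
  g <- group_meals(r)
  expect_equal(g$meal_order, 1:2)
  expect_equal(g$time, c(540L, 780L))

  empty <- person_day_recall(mk_demog(), mk_entry()[0, ])
  expect_equal(nrow(group_meals(empty)), 0)
})

test_that("grouping tolerance merges nearby times by single linkage", {
  r <- mk_recall(mk_demog(),
                 mk_entry(idx = 1, time = 540),
                 mk_entry(idx = 2, time = 545),
                 mk_entry(idx = 3, time = 551),
                 mk_entry(idx = 4, time = 700))
  expect_equal(nrow(group_meals(r, tolerance_minutes = 0)), 4)
  g <- group_meals(r, tolerance_minutes = 6)
  expect_equal(nrow(g), 2)   # chain 540-545-551, then 700
  expect_equal(g$n_entries, c(3L, 1L))
})

test_that("every entry lands in exactly one group (partition property)", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    entries <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      mk_entry(idx = j, time = sample(300:1300, 1))
    }))
    r <- person_day_recall(mk_demog(), entries)
    tol <- sample(c(0, 10, 30), 1)
    g <- group_meals(r, tol)
    got <- sort(unlist(g$entry_indices))
    expect_equal(got, seq_len(n))
    expect_lte(nrow(g), n)
  }
})

test_that("meal frequency counts breast-milk-only groups on demand", {
  r <- mk_recall(mk_demog(bf = 2L),
                 mk_entry(idx = 1, time = 540),
                 mk_entry(idx = 2, time = 700, bf = TRUE),
                 mk_entry(idx = 3, time = 780),
                 mk_entry(idx = 4, time = 900, bf = TRUE),
                 mk_entry(idx = 5, time = 1200))
  expect_equal(meal_frequency(r, include_breastmilk = TRUE), 5)
  expect_equal(meal_frequency(r, include_breastmilk = FALSE), 3)

  all_bf <- mk_recall(mk_demog(bf = 3L),
                      mk_entry(idx = 1, time = 400, bf = TRUE),
                      mk_entry(idx = 2, time = 800, bf = TRUE),
                      mk_entry(idx = 3, time = 1100, bf = TRUE))
  expect_equal(meal_frequency(all_bf, TRUE), 3)
  expect_equal(meal_frequency(all_bf, FALSE), 0)
})

test_that("energy by meal order matches hand arithmetic for one person", {
  # meals of 300/500/700 kcal: shares 0.2, 1/3, 7/15
  fct <- fct_table(tibble::tibble(
    code = c("E1", "E2", "E3"), name = c("a", "b", "c"),
    food_group = "cereals", edible_fraction = 1,
    energy_kcal = c(300, 500, 700), protein_g = 0, animal_protein_g = 0,
    fat_g = 0, carb_g = 0, fiber = 0, calcium_mg = 0, iron_mg = 0,
    zinc_mg = 0, vitA_ug_RE = 0, folate_ug = 0))
  db <- portion_db(tibble::tibble(
    food_code_or_group = "cereals", utensil = "cup", size = "medium",
    grams_per_unit = 100, provenance = ""))
  r <- mk_recall(mk_demog(),
                 mk_entry(idx = 1, time = 540, code = "E1", desc = "a"),
                 mk_entry(idx = 2, time = 780, code = "E2", desc = "b"),
                 mk_entry(idx = 3, time = 1200, code = "E3", desc = "c"))
  it <- personday_intake(r, fct_context(fct), db)
  mt <- cohort_meal_table(list(r), list(it))
  out <- energy_by_meal_order(mt, strata = character())
  expect_equal(out$mean_energy_kcal, c(300, 500, 700))
  expect_equal(out$energy_share, c(0.2, 1 / 3, 700 / 1500))

  # conservation: sum over positions of mean x n equals total daily energy
  expect_equal(sum(out$mean_energy_kcal * out$n), 1500)
})

test_that("energy by meal order averages across persons and drops empty strata", {
  mt <- tibble::tibble(
    participant_id = c("A", "A", "B", "B", "B"),
    recall_date = as.Date("2019-03-11"),
    sex = c("male", "male", "female", "female", "female"),
    age_value = 30, age_unit = "years", weekday = "Mon",
    meal_order = c(1L, 2L, 1L, 2L, 3L), time = c(540L, 800L, 500L, 820L, 1200L),
    energy_kcal = c(400, 600, 300, 500, 200),
    away_energy_kcal = 0, n_entries = 1L, all_breastmilk = FALSE)
  out <- energy_by_meal_order(mt, strata = "sex")
  male <- out[out$sex == "male", ]
  expect_equal(male$mean_energy_kcal, c(400, 600))
  expect_equal(male$energy_share, c(0.4, 0.6))
  # no meal_order 3 row for males (absent, not zero)
  expect_false(any(out$sex == "male" & out$meal_order == 3))
})

test_that("FAFH share is away energy over total energy with safe degenerate cases", {
  fct <- test_fct()
  db <- test_portion_db()
  ctx <- test_context()
  home <- test_recall_3meals()
  home$entries$location <- "home"
  expect_equal(fafh_energy_share(personday_intake(home, ctx, db)), 0)

  away <- test_recall_3meals()
  away$entries$location <- "restaurant"
  expect_equal(fafh_energy_share(personday_intake(away, ctx, db)), 1)

  # 400 kcal at home + 600 kcal in a restaurant -> 0.6
  fct2 <- fct_table(tibble::tibble(
    code = c("E1", "E2"), name = c("a", "b"), food_group = "cereals",
    edible_fraction = 1, energy_kcal = c(400, 600), protein_g = 0,
    animal_protein_g = 0, fat_g = 0, carb_g = 0, fiber = 0,
    calcium_mg = 0, iron_mg = 0, zinc_mg = 0, vitA_ug_RE = 0,
    folate_ug = 0))
  db2 <- portion_db(tibble::tibble(
    food_code_or_group = "cereals", utensil = "cup", size = "medium",
    grams_per_unit = 100, provenance = ""))
  r <- mk_recall(mk_demog(),
                 mk_entry(idx = 1, time = 540, code = "E1", desc = "a"),
                 mk_entry(idx = 2, time = 800, code = "E2", desc = "b",
                          loc = "restaurant"))
  expect_equal(fafh_energy_share(personday_intake(r, fct_context(fct2),
                                                  db2)), 0.6)

  # zero-energy day: undefined share, no division error
  bf_only <- mk_recall(mk_demog(bf = 1L), mk_entry(idx = 1, bf = TRUE))
  expect_true(is.na(fafh_energy_share(
    personday_intake(bf_only, ctx, db))))
})

test_that("food frequency ranks by count with alphabetical tie-breaks", {
  recalls <- list(
    mk_recall(mk_demog("P1"),
              mk_entry(idx = 1, time = 500, desc = "ugali"),
              mk_entry(idx = 2, time = 700, desc = "ugali"),
              mk_entry(idx = 3, time = 900, desc = "beans")),
    mk_recall(mk_demog("P2"),
              mk_entry("P2", idx = 1, time = 520, desc = "ugali"),
              mk_entry("P2", idx = 2, time = 720, desc = "chapati"),
              mk_entry("P2", idx = 3, time = 950, desc = "beans")))
  tb <- food_frequency_table(recalls)
  expect_equal(tb$food[1:2], c("ugali", "beans"))
  expect_equal(tb$count[1:2], c(3L, 2L))
  # beans and chapati would tie at 1 each if beans appeared once; force a tie
  tie <- food_frequency_table(recalls, top_n = 2)
  expect_equal(nrow(tie), 2)

  # stratified counts match brute force
  strat <- food_frequency_table(recalls,
                                stratifier = function(r) {
                                  r$demographics$participant_id
                                })
  expect_equal(strat$count[strat$stratum == "P1" & strat$food == "ugali"],
               2L)
})

test_that("timing histogram conserves group counts and validates bins", {
  recalls <- list(
    mk_recall(mk_demog("P1"),
              mk_entry(idx = 1, time = 540),
              mk_entry(idx = 2, time = 570),
              mk_entry(idx = 3, time = 1200)),
    mk_recall(mk_demog("P2"), mk_entry("P2", idx = 1, time = 545)))
  h <- timing_histogram(recalls, bin_minutes = 60)
  expect_equal(h$count[h$bin_start == 540], 3L)
  expect_equal(sum(h$count),
               sum(vapply(recalls, function(r) nrow(group_meals(r)),
                          integer(1))))
  expect_error(timing_histogram(recalls, bin_minutes = 37),
               "must divide 1440")
})

test_that("density mode recovery finds well-separated mixture modes", {
  set.seed(17)
  times <- c(stats::rnorm(400, 540, 35), stats::rnorm(400, 810, 45),
             stats::rnorm(300, 1150, 35))
  modes <- recover_timing_modes(times, k = 3)
  expect_length(modes, 3)
  expect_lt(abs(modes[1] - 540), 25)
  expect_lt(abs(modes[2] - 810), 25)
  expect_lt(abs(modes[3] - 1150), 25)
})
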