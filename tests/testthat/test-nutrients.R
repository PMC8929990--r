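test_that("meal nutrients scale linearly with grams and honor exclusions", {
  ctx <- test_context()
  res <- resolve_code("101", primary = ctx$primary)
  v100 <- meal_nutrients(mk_entry(), res, 100)
  item <- test_fct_items()[1, ]
  expect_false(v100$excluded)
  expect_equal(v100$nutrients,
               stats::setNames(as.numeric(item[1, nutrient_names()]),
                               nutrient_names()))
  v250 <- meal_nutrients(mk_entry(), res, 250)
  expect_equal(v250$nutrients, 2.5 * v100$nutrients)

  bf <- meal_nutrients(mk_entry(bf = TRUE), NULL, NA)
  expect_true(bf$excluded)
  expect_equal(bf$reason, "breast_milk")
  expect_equal(bf$nutrients, nv_zero())

  un <- meal_nutrients(mk_entry(code = "404"),
                       resolve_code("404", primary = ctx$primary), NA)
  expect_true(un$excluded)
  expect_equal(un$reason, "unresolved")

  expect_error(meal_nutrients(mk_entry(), res, -5), ">= 0")
})

test_that("edible fraction converts as-served grams before the per-100 g multiply", {
  ctx <- test_context()
  res <- resolve_code("103", primary = ctx$primary)   # mango, ef 0.7
  v <- meal_nutrients(mk_entry(code = "103"), res, 100)
  item <- test_fct_items()[3, ]
  expect_equal(v$nutrients,
               0.7 * stats::setNames(as.numeric(item[1, nutrient_names()]),
                                     nutrient_names()))
})

test_that("person-day totals equal the hand-summed fixture vector", {
  it <- personday_intake(test_recall_3meals(), test_context(),
                         test_portion_db())
  expect_equal(it$totals, test_recall_3meals_totals())
  expect_equal(it$meal_frequency_incl_bf, 3)
  expect_equal(it$meal_frequency_excl_bf, 3)
  expect_equal(it$n_unresolved, 0)
  # totals are the componentwise sum of non-excluded per-meal rows
  nut <- as.matrix(it$meals[!it$meals$excluded, nutrient_names()])
  expect_equal(stats::setNames(colSums(nut), nutrient_names()), it$totals)
})

test_that("breast-milk entries change meal frequency but never nutrient totals", {
  base <- test_recall_3meals()
  it0 <- personday_intake(base, test_context(), test_portion_db())
  with_bf <- person_day_recall(
    mk_demog(bf = 1L),
    dplyr::bind_rows(base$entries, mk_entry(idx = 4, time = 360, bf = TRUE)))
  it1 <- personday_intake(with_bf, test_context(), test_portion_db())
  expect_equal(it1$totals, it0$totals)
  expect_equal(it1$meal_frequency_incl_bf, it0$meal_frequency_incl_bf + 1)
  expect_equal(it1$meal_frequency_excl_bf, it0$meal_frequency_excl_bf)
})

test_that("unresolved foods contribute zero and are counted, not fatal", {
  r <- mk_recall(mk_demog(),
                 mk_entry(idx = 1, code = "101"),
                 mk_entry(idx = 2, time = 700, code = "9999",
                          desc = "mystery stew"))
  it <- personday_intake(r, test_context(), test_portion_db())
  expect_equal(it$n_unresolved, 1)
  only_first <- personday_intake(
    mk_recall(mk_demog(), mk_entry(idx = 1, code = "101")),
    test_context(), test_portion_db())
  expect_equal(it$totals, only_first$totals)
})

test_that("a recall with zero food entries has zero totals", {
  r <- mk_recall(mk_demog(bf = 2L),
                 mk_entry(idx = 1, time = 400, bf = TRUE),
                 mk_entry(idx = 2, time = 800, bf = TRUE))
  it <- personday_intake(r, test_context(), test_portion_db())
  expect_equal(it$totals, nv_zero())
  expect_equal(it$meal_frequency_incl_bf, 2)
  expect_equal(it$meal_frequency_excl_bf, 0)
})

test_that("RNI adequacy ratios classify intakes against the bundled table", {
  profile <- list(age_months = 10, sex = "female", breastfed = TRUE)
  # adjusted folate RNI for a breastfed 9-11-mo child is 27.6 ug/d
  tot <- nv_zero()
  tot["folate_ug"] <- 35.6
  adq <- rni_adequacy(tot, profile)
  fol <- adq[adq$nutrient == "folate_ug", ]
  expect_equal(fol$rni, 27.6)
  expect_true(fol$meets)
  expect_equal(fol$ratio, 35.6 / 27.6)

  # intake equal to the RNI meets it; zero intake does not
  tot2 <- nv_zero(); tot2["folate_ug"] <- 27.6
  expect_true(rni_adequacy(tot2, profile)$meets[
    rni_adequacy(tot2, profile)$nutrient == "folate_ug"])
  zero <- rni_adequacy(nv_zero(), profile)
  expect_false(zero$meets[zero$nutrient == "folate_ug"])
  expect_equal(zero$ratio[zero$nutrient == "folate_ug"], 0)

  # non-breastfed profiles see the unadjusted row
  un <- rni_adequacy(tot, list(age_months = 10, sex = "female",
                               breastfed = FALSE))
  expect_equal(un$rni[un$nutrient == "folate_ug"], 80)

  # nutrients without a matching band are not evaluable
  expect_false(any(rni_adequacy(tot, list(age_months = 3,
                                          sex = "female"))$evaluable[
    rni_adequacy(tot, list(age_months = 3, sex = "female"))$nutrient ==
      "energy_kcal"]))
})

test_that("energy-range classification uses the printed breastfed bounds inclusively", {
  # 7 mo, 650 kcal: above the 100-600 band
  r1 <- energy_range_check(650, 7, TRUE)
  expect_equal(r1$classification, "above")
  expect_equal(c(r1$lower_kcal, r1$upper_kcal), c(100, 600))
  # 15 mo, 500 kcal: exactly on the lower bound of 500-1100 -> within
  r2 <- energy_range_check(500, 15, TRUE)
  expect_equal(r2$classification, "within")
  expect_equal(c(r2$lower_kcal, r2$upper_kcal), c(500, 1100))
  # 10 mo, 150 kcal: below the 200-750 band
  r3 <- energy_range_check(150, 10, TRUE)
  expect_equal(r3$classification, "below")
  expect_equal(c(r3$lower_kcal, r3$upper_kcal), c(200, 750))
  # no non-breastfed ranges ship by default
  expect_equal(energy_range_check(500, 15, FALSE)$classification,
               "not_evaluable")
  # uncovered age
  expect_equal(energy_range_check(500, 30, TRUE)$classification,
               "not_evaluable")
})

test_that("intake_table flattens totals and frequencies", {
  it <- personday_intake(test_recall_3meals(), test_context(),
                         test_portion_db())
  tb <- intake_table(list(it))
  expect_equal(nrow(tb), 1)
  expect_equal(tb$energy_kcal, it$totals[["energy_kcal"]])
  expect_equal(tb$meal_frequency_incl_bf, 3)
})
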