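test_that("load_fct parses a fixture file with fields preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(test_fct_items()[1:3, ], path)
  fct <- load_fct(path)
  expect_s3_class(fct, "fct_table")
  expect_equal(nrow(fct$items), 3)
  expect_equal(fct$items$code, c("101", "102", "103"))
  expect_equal(fct$items$edible_fraction, c(1, 1, 0.7))
  expect_equal(fct$items$energy_kcal, c(60, 200, 60))
  expect_equal(fct$items$folate_ug, c(15, 8, 43))
})

test_that("load_fct accepts tab-delimited files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(test_fct_items(), path)
  fct <- load_fct(path)
  expect_equal(nrow(fct$items), 4)
})

test_that("load_fct rejects duplicate codes naming both rows", {
  items <- test_fct_items()[c(1, 2, 1), ]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(items, path)
  expect_error(load_fct(path), "duplicate food code.*101.*rows 1 and 3")
})

test_that("load_fct handles a header-only file, missing nutrient columns, and bad values", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(test_fct_items()[0, ], path)
  expect_equal(nrow(load_fct(path)$items), 0)

  partial <- test_fct_items()[, 1:8]   # drops carb onwards
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(partial, path2)
  expect_warning(fct <- load_fct(path2), "defaulting to 0")
  expect_true(all(fct$items$folate_ug == 0))

  neg <- test_fct_items()
  neg$iron_mg[2] <- -1
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(neg, path3)
  expect_error(load_fct(path3), "negative nutrient")

  sent <- test_fct_items()
  sent$code[1] <- "9999"
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sent, path4)
  expect_error(load_fct(path4), "sentinel")
})

test_that("FCT write-back and reload reproduces all items exactly", {
  fct <- test_fct()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fct(fct, path)
  again <- load_fct(path)
  expect_equal(again$items, fct$items)
})

test_that("nutrient vectors enforce their invariants", {
  v <- nutrient_vector(energy_kcal = 100, protein_g = 5,
                       animal_protein_g = 2)
  expect_equal(v[["energy_kcal"]], 100)
  expect_equal(sum(v > 0), 3)
  expect_error(nutrient_vector(protein_g = -1), ">= 0")
  expect_error(nutrient_vector(protein_g = 1, animal_protein_g = 2),
               "animal_protein_g exceeds")
  expect_error(nutrient_vector(bogus = 1), "unknown nutrient")
})

test_that("resolve_code walks the cascade in order", {
  ctx <- test_context()
  # direct primary hit
  r1 <- resolve_code("102", primary = ctx$primary, secondary = ctx$secondary)
  expect_equal(r1$source, "primary_fct")
  expect_equal(r1$item$name, "beef relish")

  # unknown code assigned to a secondary-table code
  r2 <- resolve_code("9999", description = "sorghum porridge",
                     primary = ctx$primary, secondary = ctx$secondary,
                     assignments = list("sorghum porridge" = "K01"))
  expect_equal(r2$source, "secondary_fct")
  expect_equal(r2$item$code, "K01")

  # entry-id key takes precedence over the description key
  r2b <- resolve_code("9999", description = "sorghum porridge",
                      primary = ctx$primary, secondary = ctx$secondary,
                      assignments = list("P1|2019-03-11|4" = "101",
                                         "sorghum porridge" = "K01"),
                      entry_id = "P1|2019-03-11|4")
  expect_equal(r2b$source, "primary_fct")

  # exhausted cascade
  r3 <- resolve_code("9999", description = "unknown stew",
                     primary = ctx$primary, secondary = ctx$secondary)
  expect_equal(r3$source, "unresolved")
  expect_null(r3$item)
  expect_match(r3$audit, "no assignment")

  # non-sentinel code absent everywhere is unresolved, not an error
  r4 <- resolve_code("777", primary = ctx$primary,
                     secondary = ctx$secondary)
  expect_equal(r4$source, "unresolved")
})

test_that("new-recipe sentinel resolves through the registry or degrades gracefully", {
  ctx <- test_context()
  reg <- recipe_registry(list(
    recipe("R001", "porridge with mango",
           data.frame(code = c("101", "103"), grams = c(100, 100)),
           cooked_weight_g = 200)))
  r <- resolve_code("8888", primary = ctx$primary,
                    secondary = ctx$secondary,
                    assignments = list("e1" = "R001"), recipes = reg,
                    entry_id = "e1")
  expect_equal(r$source, "recipe")
  expect_equal(r$item$code, "R001")
  expect_equal(r$item$edible_fraction, 1)

  # 8888 with no recipe assigned: unresolved with a distinct audit message
  r2 <- resolve_code("8888", primary = ctx$primary)
  expect_equal(r2$source, "unresolved")
  expect_match(r2$audit, "no recipe assigned")
})

test_that("resolve_code is a pure function of its inputs", {
  ctx <- test_context()
  args <- list("9999", description = "sorghum porridge",
               primary = ctx$primary, secondary = ctx$secondary,
               assignments = list("sorghum porridge" = "K01"))
  a <- do.call(resolve_code, args)
  b <- do.call(resolve_code, args)
  expect_identical(a, b)
})
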