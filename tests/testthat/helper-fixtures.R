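# Hand-built fixtures shared across tests. All values are chosen so that
# expected results can be verified by short hand arithmetic.

test_fct_items <- function() {
  tibble::tibble(
    code = c("101", "102", "103", "104"),
    name = c("maize porridge", "beef relish", "mango ripe", "black tea"),
    food_group = c("cereals", "meat", "fruits", "beverages"),
    edible_fraction = c(1, 1, 0.7, 1),
    energy_kcal = c(60, 200, 60, 1),
    protein_g = c(1.5, 20, 0.5, 0),
    animal_protein_g = c(0, 20, 0, 0),
    fat_g = c(0.8, 13, 0.3, 0),
    carb_g = c(12, 0, 15, 0.2),
    fiber = c(1, 0, 1.8, 0),
    calcium_mg = c(10, 15, 11, 2),
    iron_mg = c(0.4, 2.5, 0.2, 0.1),
    zinc_mg = c(0.3, 5, 0.1, 0),
    vitA_ug_RE = c(2, 10, 54, 0),
    folate_ug = c(15, 8, 43, 1)
  )
}

test_fct <- function(label = "primary") fct_table(test_fct_items(), label)

test_secondary_fct <- function() {
  items <- test_fct_items()[1, ]
  items$code <- "K01"
  items$name <- "sorghum porridge"
  fct_table(items, "secondary")
}

test_portion_entries <- function() {
  tibble::tibble(
    food_code_or_group = c("101", "102", "cereals", "meat", "fruits",
                           "beverages"),
    utensil = c("cup", "plate", "bowl", "plate", "plate", "cup"),
    size = c("medium", "medium", "medium", "medium", "small", "medium"),
    grams_per_unit = c(240, 150, 300, 100, 120, 250),
    provenance = "test fixture"
  )
}

test_portion_db <- function() portion_db(test_portion_entries())

mk_demog <- function(pid = "P1", date = "2019-03-11", cohort = "adults",
                     age = 30, unit = "years", sex = "female",
                     day = "typical", supp = FALSE, bf = 0L) {
  tibble::tibble(participant_id = pid, recall_date = as.Date(date),
                 cohort = cohort, age_value = age, age_unit = unit,
                 sex = sex, day_character = day, supplement_use = supp,
                 declared_bf_frequency = as.integer(bf))
}

mk_entry <- function(pid = "P1", date = "2019-03-11", idx = 1L, time = 540L,
                     loc = "home", code = "101", desc = "maize porridge",
                     utensil = "cup", size = "medium", pc = 1,
                     bf = FALSE, ingredients = "", comments = "") {
  tibble::tibble(participant_id = pid, recall_date = as.Date(date),
                 entry_index = as.integer(idx), clock_time = as.integer(time),
                 location = loc, food_code = code, description = desc,
                 ingredients = ingredients, utensil = utensil,
                 utensil_size = size,
                 portion_count = if (bf) NA_real_ else pc,
                 is_breastmilk = bf, comments = comments)
}

mk_recall <- function(demog, ...) {
  person_day_recall(demog, dplyr::bind_rows(...))
}

test_context <- function() {
  fct_context(test_fct(), test_secondary_fct())
}

# A three-meal adult recall with known hand-computable intake:
#  09:00 home   1 medium cup of 101  -> 240 g
#  13:00 home   2 medium plates of 102 -> 300 g
#  18:30 restaurant 1 small plate of 103 -> 120 g (edible fraction 0.7)
test_recall_3meals <- function() {
  mk_recall(
    mk_demog(),
    mk_entry(idx = 1, time = 540, code = "101", desc = "maize porridge",
             utensil = "cup", size = "medium", pc = 1),
    mk_entry(idx = 2, time = 780, code = "102", desc = "beef relish",
             utensil = "plate", size = "medium", pc = 2),
    mk_entry(idx = 3, time = 1110, loc = "restaurant", code = "103",
             desc = "mango ripe", utensil = "plate", size = "small", pc = 1)
  )
}

# Hand-summed totals for test_recall_3meals():
#   2.4 * v101 + 3.0 * v102 + 1.2 * 0.7 * v103
test_recall_3meals_totals <- function() {
  it <- test_fct_items()
  v <- function(code) {
    r <- it[it$code == code, ]
    stats::setNames(as.numeric(r[1, nutrient_names()]), nutrient_names())
  }
  2.4 * v("101") + 3.0 * v("102") + 0.84 * v("103")
}
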