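write_fixture_tables <- function(demog, meals, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  dp <- file.path(dir, "demog.csv")
  mp <- file.path(dir, "meals.csv")
  m <- meals
  m$clock_time <- sprintf("%02d:%02d", m$clock_time %/% 60,
                          m$clock_time %% 60)
  readr::write_csv(demog, dp, na = "")
  readr::write_csv(m, mp, na = "")
  list(demog = dp, meals = mp)
}

test_that("two-participant fixture joins 3 + 4 meal rows to two recalls", {
  demog <- dplyr::bind_rows(mk_demog("P1"), mk_demog("P2", sex = "male"))
  meals <- dplyr::bind_rows(
    mk_entry("P1", idx = 1, time = 540), mk_entry("P1", idx = 2, time = 780),
    mk_entry("P1", idx = 3, time = 1200),
    mk_entry("P2", idx = 1, time = 500), mk_entry("P2", idx = 2, time = 800),
    mk_entry("P2", idx = 3, time = 1000), mk_entry("P2", idx = 4, time = 1230))
  p <- write_fixture_tables(demog, meals)
  recalls <- read_recall_tables(p$demog, p$meals)
  expect_length(recalls, 2)
  expect_equal(vapply(recalls, function(r) nrow(r$entries), integer(1)),
               c(3L, 4L))
  # conservation: total entries equal the meal-file row count
  expect_equal(sum(vapply(recalls, function(r) nrow(r$entries),
                          integer(1))), nrow(meals))
})

test_that("orphan meal rows and duplicate demographics keys are errors", {
  demog <- mk_demog("P1")
  meals <- dplyr::bind_rows(mk_entry("P1"), mk_entry("P9"))
  p <- write_fixture_tables(demog, meals)
  expect_error(read_recall_tables(p$demog, p$meals),
               "no matching demographics.*P9")

  demog2 <- dplyr::bind_rows(mk_demog("P1"), mk_demog("P1"))
  p2 <- write_fixture_tables(demog2, mk_entry("P1"))
  expect_error(read_recall_tables(p2$demog, p2$meals),
               "duplicate \\(participant_id, recall_date\\)")
})

test_that("a demographics row with no meals yields an empty recall and a note", {
  demog <- dplyr::bind_rows(mk_demog("P1"), mk_demog("P2"))
  p <- write_fixture_tables(demog, mk_entry("P1"))
  expect_message(recalls <- read_recall_tables(p$demog, p$meals),
                 "P2.*no meal rows")
  expect_equal(nrow(recalls[[2]]$entries), 0)
})

test_that("unrecognized locations downgrade to 'other' with a warning", {
  demog <- mk_demog("P1")
  meals <- mk_entry("P1")
  meals$location <- "street corner"
  p <- write_fixture_tables(demog, meals)
  expect_warning(recalls <- read_recall_tables(p$demog, p$meals),
                 "street corner")
  expect_equal(recalls[[1]]$entries$location, "other")
})

test_that("column mapping renames alternative headers", {
  demog <- mk_demog("P1")
  names(demog)[names(demog) == "participant_id"] <- "pid"
  meals <- mk_entry("P1")
  names(meals)[names(meals) == "participant_id"] <- "pid"
  p <- write_fixture_tables(demog, meals)
  recalls <- read_recall_tables(p$demog, p$meals,
                                column_map = c(participant_id = "pid"))
  expect_equal(recalls[[1]]$demographics$participant_id, "P1")
})

test_that("round trip is lossless across every enum level and embedded delimiters", {
  locs <- location_levels()
  days <- day_character_levels()
  demog <- dplyr::bind_rows(lapply(seq_along(days), function(i) {
    mk_demog(sprintf("P%d", i), day = days[i],
             cohort = ifelse(i %% 2, "adults", "children"))
  }))
  meals <- dplyr::bind_rows(lapply(seq_along(locs), function(i) {
    mk_entry("P1", idx = i, time = 400 + 60 * i, loc = locs[i],
             desc = "rice, boiled \"plain\", with oil",
             ingredients = "rice:T1;oil:T2",
             comments = "shared, ate half; spoon, not cup")
  }))
  recalls <- suppressMessages(assemble_recalls(demog, meals))
  dir <- withr::local_tempdir()
  paths <- write_normalized(recalls, file.path(dir, "d.csv"),
                            file.path(dir, "m.csv"))
  again <- suppressMessages(read_recall_tables(paths[["demographics"]],
                                               paths[["meals"]]))
  expect_length(again, length(recalls))
  for (i in seq_along(recalls)) {
    expect_equal(again[[i]]$demographics, recalls[[i]]$demographics)
    expect_equal(again[[i]]$entries, recalls[[i]]$entries)
  }
  expect_setequal(again[[1]]$entries$location, locs)
})

test_that("an empty recall list writes header-only files that read back empty", {
  dir <- withr::local_tempdir()
  paths <- write_normalized(list(), file.path(dir, "d.csv"),
                            file.path(dir, "m.csv"))
  expect_length(readr::read_lines(paths[["demographics"]]), 1)
  recalls <- read_recall_tables(paths[["demographics"]], paths[["meals"]])
  expect_length(recalls, 0)
})

test_that("entry invariants are enforced at construction", {
  expect_error(mk_recall(mk_demog(), mk_entry(idx = 1), mk_entry(idx = 1)),
               "duplicate entry_index")
  bad <- mk_entry(idx = 1)
  bad$clock_time <- 1500L
  expect_error(mk_recall(mk_demog(), bad), "clock_time")
  bad2 <- mk_entry(idx = 1, pc = 0)
  expect_error(mk_recall(mk_demog(), bad2), "portion_count")
  # breast-milk entries need no portion
  ok <- mk_recall(mk_demog(bf = 1L), mk_entry(idx = 1, bf = TRUE))
  expect_s3_class(ok, "person_day_recall")
})

test_that("clock-time parsing accepts HH:MM and rejects malformed strings", {
  expect_equal(parse_clock_time(c("00:00", "8:05", "23:59")),
               c(0L, 485L, 1439L))
  expect_error(parse_clock_time("25:00"), "unparseable")
  expect_error(parse_clock_time("8h30"), "unparseable")
})
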