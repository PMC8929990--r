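#' Enumerations used by the recall export
#'
#' `location_levels()` are the eight meal locations recorded by the
#' interview (including *mamalishe*, women food vendors preparing street
#' meals); `day_character_levels()` characterize the consumption day.
#'
#' @return Character vector of levels.
#' @export
location_levels <- function() {
  c("home", "work", "friend_house", "roadside_vendor", "mamalishe",
    "restaurant", "hotel", "other")
}

#' @rdname location_levels
#' @export
day_character_levels <- function() {
  c("typical", "holiday_special", "fasting", "other")
}

demographics_columns <- function() {
  c("participant_id", "recall_date", "cohort", "age_value", "age_unit",
    "sex", "day_character", "supplement_use", "declared_bf_frequency")
}

meal_columns <- function() {
  c("participant_id", "recall_date", "entry_index", "clock_time", "location",
    "food_code", "description", "ingredients", "utensil", "utensil_size",
    "portion_count", "is_breastmilk", "comments")
}

parse_logical_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  if (anyNA(out[!is.na(lx)])) {
    bad <- unique(x[!is.na(lx) & is.na(out)])
    stop("unparseable ", what, " value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

normalize_levels <- function(x, levels, what) {
  norm <- gsub("[ '-]+", "_", tolower(trimws(as.character(x))))
  bad <- !is.na(norm) & !(norm %in% levels)
  if (any(bad)) {
    warning("unrecognized ", what, " value(s) mapped to 'other': ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    norm[bad] <- "other"
  }
  norm
}

recall_key <- function(participant_id, recall_date) {
  paste(participant_id, as.character(recall_date), sep = "|")
}

#' One person-day of recall data
#'
#' Joins one demographics record to its ordered meal entries. Normally
#' produced by [read_recall_tables()] or [assemble_recalls()].
#'
#' @param demographics One-row tibble over the demographics schema.
#' @param entries Tibble over the meals schema (may have zero rows), ordered
#'   by `entry_index`.
#' @return Object of class `person_day_recall`.
#' @export
person_day_recall <- function(demographics, entries) {
  demographics <- tibble::as_tibble(demographics)
  entries <- tibble::as_tibble(entries)
  stopifnot(nrow(demographics) == 1L)
  key <- recall_key(demographics$participant_id, demographics$recall_date)
  if (nrow(entries)) {
    ekeys <- recall_key(entries$participant_id, entries$recall_date)
    if (!all(ekeys == key)) {
      stop("meal entries do not all match the demographics key ", key,
           call. = FALSE)
    }
    if (anyDuplicated(entries$entry_index)) {
      stop("duplicate entry_index values for ", key, call. = FALSE)
    }
    if (any(entries$clock_time < 0 | entries$clock_time >= 1440)) {
      stop("clock_time out of [0, 1440) for ", key, call. = FALSE)
    }
    bad_pc <- !entries$is_breastmilk &
      (is.na(entries$portion_count) | entries$portion_count <= 0)
    if (any(bad_pc)) {
      stop("portion_count must be > 0 for food entries (", key,
           ", entry ", paste(entries$entry_index[bad_pc], collapse = ", "),
           ")", call. = FALSE)
    }
    entries <- entries[order(entries$entry_index), , drop = FALSE]
  }
  structure(list(demographics = demographics, entries = entries),
            class = "person_day_recall")
}

#' @export
print.person_day_recall <- function(x, ...) {
  d <- x$demographics
  cat(sprintf("<person_day_recall %s @ %s: %d entries (%d breast-milk)>\n",
              d$participant_id, as.character(d$recall_date),
              nrow(x$entries), sum(x$entries$is_breastmilk)))
  invisible(x)
}

prepare_demographics <- function(d, origin = "demographics") {
  missing_cols <- setdiff(demographics_columns(), names(d))
  if (length(missing_cols)) {
    stop(origin, " table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(d)[, demographics_columns()]
  d$participant_id <- as.character(d$participant_id)
  d$recall_date <- as.Date(d$recall_date)
  d$cohort <- as.character(d$cohort)
  d$age_value <- as.numeric(d$age_value)
  d$age_unit <- tolower(as.character(d$age_unit))
  bad_unit <- !d$age_unit %in% c("months", "years")
  if (any(bad_unit)) {
    stop("age_unit must be 'months' or 'years'; got: ",
         paste(unique(d$age_unit[bad_unit]), collapse = ", "), call. = FALSE)
  }
  d$sex <- tolower(as.character(d$sex))
  d$day_character <- normalize_levels(d$day_character, day_character_levels(),
                                      "day_character")
  d$supplement_use <- parse_logical_flag(d$supplement_use, "supplement_use")
  d$declared_bf_frequency <- as.integer(d$declared_bf_frequency)
  keys <- recall_key(d$participant_id, d$recall_date)
  if (anyDuplicated(keys)) {
    stop("duplicate (participant_id, recall_date) in demographics: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  d
}

prepare_meals <- function(m, origin = "meals") {
  required <- setdiff(meal_columns(), c("ingredients", "comments"))
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    stop(origin, " table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- tibble::as_tibble(m)
  if (is.null(m$ingredients)) m$ingredients <- ""
  if (is.null(m$comments)) m$comments <- ""
  m <- m[, meal_columns()]
  m$participant_id <- as.character(m$participant_id)
  m$recall_date <- as.Date(m$recall_date)
  m$entry_index <- as.integer(m$entry_index)
  if (is.character(m$clock_time)) {
    m$clock_time <- parse_clock_time(m$clock_time)
  } else {
    m$clock_time <- as.integer(m$clock_time)
  }
  m$location <- normalize_levels(m$location, location_levels(), "location")
  for (col in c("food_code", "description", "ingredients", "utensil",
                "utensil_size", "comments")) {
    m[[col]] <- as.character(m[[col]])
    m[[col]][is.na(m[[col]])] <- ""
  }
  m$portion_count <- as.numeric(m$portion_count)
  m$is_breastmilk <- parse_logical_flag(m$is_breastmilk, "is_breastmilk")
  m
}

#' Read the two-table recall export
#'
#' Reads the demographics file (one record per participant per recall day)
#' and the meals file (multiple records per participant per day), validates
#' the join, and returns one [person_day_recall()] per demographics row.
#' Participants with zero meal rows are returned with empty entries and
#' noted via a message. A meal row with no matching demographics row is an
#' error listing the orphan keys.
#'
#' @param demog_path,meals_path Delimited files (comma default, tab
#'   accepted) over the documented schemas.
#' @param column_map Optional named character vector renaming file headers
#'   to canonical names, as `c(canonical = "file_header", ...)`.
#' @param delim Delimiter override applied to both files.
#' @return List of `person_day_recall`, in demographics file order.
#' @export
read_recall_tables <- function(demog_path, meals_path, column_map = NULL,
                               delim = NULL) {
  for (p in c(demog_path, meals_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  read_one <- function(path) {
    readr::read_delim(path, delim = sniff_delim(path, delim),
                      show_col_types = FALSE, progress = FALSE,
                      na = "", col_types = readr::cols(.default = readr::col_character()))
  }
  d <- read_one(demog_path)
  m <- read_one(meals_path)
  if (!is.null(column_map)) {
    rename_with_map <- function(tb) {
      hit <- column_map[column_map %in% names(tb)]
      names(tb)[match(hit, names(tb))] <- names(hit)
      tb
    }
    d <- rename_with_map(d)
    m <- rename_with_map(m)
  }
  assemble_recalls(d, m)
}

#' Assemble recalls from in-memory tables
#'
#' The same join and validation as [read_recall_tables()], starting from
#' tibbles (e.g. those produced by [generate_recalls()]).
#'
#' @param demographics,meals Tables over the documented schemas.
#' @return List of `person_day_recall`.
#' @export
assemble_recalls <- function(demographics, meals) {
  d <- prepare_demographics(demographics)
  m <- prepare_meals(meals)
  dkeys <- recall_key(d$participant_id, d$recall_date)
  mkeys <- if (nrow(m)) recall_key(m$participant_id, m$recall_date) else character()
  orphans <- setdiff(mkeys, dkeys)
  if (length(orphans)) {
    stop("meal rows with no matching demographics row: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  recalls <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    ent <- m[mkeys == dkeys[i], , drop = FALSE]
    if (nrow(ent) == 0L) {
      message("participant-day ", dkeys[i], " has no meal rows")
    }
    recalls[[i]] <- person_day_recall(d[i, , drop = FALSE], ent)
  }
  recalls
}

#' Write recalls back to the normalized two-table form
#'
#' Serializes a list of recalls to the demographics and meals files such
#' that re-reading reproduces every field (round trip), including free text
#' with embedded delimiters (quoted). Clock times are written as `"HH:MM"`.
#' An empty recall list yields header-only files.
#'
#' @param recalls List of `person_day_recall`.
#' @param out_demog_path,out_meals_path Output file paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_normalized <- function(recalls, out_demog_path, out_meals_path) {
  stopifnot(is.list(recalls),
            all(vapply(recalls, inherits, logical(1), "person_day_recall")))
  if (length(recalls)) {
    d <- dplyr::bind_rows(lapply(recalls, function(r) r$demographics))
    m <- dplyr::bind_rows(lapply(recalls, function(r) r$entries))
  } else {
    d <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(demographics_columns())),
      demographics_columns()))
    m <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(meal_columns())), meal_columns()))
  }
  if (nrow(m)) m$clock_time <- format_clock_time(m$clock_time)
  readr::write_csv(d, out_demog_path, na = "", progress = FALSE)
  readr::write_csv(m, out_meals_path, na = "", progress = FALSE)
  invisible(c(demographics = out_demog_path, meals = out_meals_path))
}
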