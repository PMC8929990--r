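#' End-of-interview summary of a recall
#'
#' The review document shown after the last meal loop: each meal group with
#' its time, locations, items and (when an intake is supplied) portion
#' grams, followed by any quality-control findings. Ordering is
#' deterministic (time, then entry index), so repeated renders are
#' byte-identical.
#'
#' @param recall A `person_day_recall`.
#' @param intake Optional matching `person_day_intake` (adds grams).
#' @param cfg A [qc_config()].
#' @param db,ctx Optional portion database and food-composition context
#'   forwarded to [validate_recall()].
#' @return Character vector of report lines.
#' @export
interview_summary <- function(recall, intake = NULL, cfg = qc_config(),
                              db = NULL, ctx = NULL) {
  d <- recall$demographics
  g <- group_meals(recall, cfg$meal_tolerance_minutes)
  lines <- c(
    sprintf("Interview summary: participant %s, recall day %s",
            d$participant_id, as.character(d$recall_date)),
    sprintf("Meals recorded: %d group(s), %d entr(ies)", nrow(g),
            nrow(recall$entries)))
  e <- recall$entries
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf(
      "Meal %d @ %s [%s]", g$meal_order[i],
      format_clock_time(g$time[i]),
      paste(sort(unlist(g$locations[i])), collapse = ", ")))
    for (ix in sort(unlist(g$entry_indices[i]))) {
      row <- e[e$entry_index == ix, , drop = FALSE]
      label <- if (row$is_breastmilk) {
        "breast milk"
      } else if (nzchar(row$description)) {
        sprintf("%s (code %s)", row$description, row$food_code)
      } else {
        sprintf("code %s", row$food_code)
      }
      grams_txt <- ""
      if (!is.null(intake)) {
        mrow <- intake$meals[intake$meals$entry_index == ix, , drop = FALSE]
        if (nrow(mrow) && !is.na(mrow$grams)) {
          grams_txt <- sprintf(", %.0f g", mrow$grams)
        }
      }
      portion_txt <- if (row$is_breastmilk) "" else {
        sprintf(" — %s %s x %s%s", row$utensil_size, row$utensil,
                format(row$portion_count), grams_txt)
      }
      lines <- c(lines, sprintf("  - %s%s", label, portion_txt))
    }
  }
  if (nrow(g) == 0L) lines <- c(lines, "No meals recorded (zero meals).")
  f <- validate_recall(recall, cfg, db = db, ctx = ctx)
  if (nrow(f)) {
    lines <- c(lines, "Findings:",
               sprintf("  [%s] %s: %s", f$severity, f$rule_id, f$message))
  } else {
    lines <- c(lines, "Findings: none")
  }
  lines
}

#' Daily field report across a roster
#'
#' The real-time monitoring report compiled each collection day: missing
#' forms (roster minus received), the distribution of first-meal times,
#' the most frequently consumed foods per meal-order position, the
#' breastfeeding-frequency distribution, and all findings. Sorting is
#' stable so reports can be diffed.
#'
#' @param recalls List of `person_day_recall` received for the date.
#' @param expected_roster Character vector of expected participant ids.
#' @param date Collection date the report covers.
#' @param top_k Foods to list per meal-order position (default 10).
#' @param cfg A [qc_config()].
#' @return Object of class `daily_report` (a list with components
#'   `date`, `missing_forms`, `first_meal_times`, `top_foods_by_order`,
#'   `bf_frequency_distribution`, `findings`, `text`).
#' @export
daily_report <- function(recalls, expected_roster, date, top_k = 10,
                         cfg = qc_config()) {
  date <- as.Date(date)
  received <- vapply(recalls, function(r) r$demographics$participant_id,
                     character(1))
  missing <- sort(setdiff(expected_roster, received))

  first_times <- sort(stats::na.omit(vapply(recalls, function(r) {
    g <- group_meals(r, cfg$meal_tolerance_minutes)
    if (nrow(g)) g$time[1] else NA_integer_
  }, integer(1))))

  per_order <- dplyr::bind_rows(lapply(recalls, function(r) {
    g <- group_meals(r, cfg$meal_tolerance_minutes)
    e <- r$entries
    if (nrow(g) == 0L) return(NULL)
    dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
      rows <- e[e$entry_index %in% unlist(g$entry_indices[i]) &
                  !e$is_breastmilk, , drop = FALSE]
      if (nrow(rows) == 0L) return(NULL)
      tibble::tibble(
        meal_order = g$meal_order[i],
        food = ifelse(nzchar(rows$description), rows$description,
                      rows$food_code))
    }))
  }))
  top_foods <- if (!is.null(per_order) && nrow(per_order)) {
    counts <- dplyr::count(per_order, .data$meal_order, .data$food,
                           name = "count")
    counts <- dplyr::arrange(counts, .data$meal_order,
                             dplyr::desc(.data$count), .data$food)
    dplyr::ungroup(dplyr::slice_head(
      dplyr::group_by(counts, .data$meal_order), n = top_k))
  } else {
    tibble::tibble(meal_order = integer(), food = character(),
                   count = integer())
  }

  bf <- table(vapply(recalls, function(r) {
    r$demographics$declared_bf_frequency
  }, integer(1)))

  findings <- dplyr::bind_rows(lapply(recalls, function(r) {
    f <- validate_recall(r, cfg)
    if (nrow(f) == 0L) return(NULL)
    f$participant_id <- r$demographics$participant_id
    f
  }))
  if (is.null(findings) || nrow(findings) == 0L) {
    findings <- empty_findings()
    findings$participant_id <- character(0)
  }

  text <- c(
    sprintf("Daily report for %s: %d/%d forms received", as.character(date),
            length(received), length(expected_roster)),
    if (length(missing)) {
      sprintf("Missing forms: %s", paste(missing, collapse = ", "))
    } else "Missing forms: none",
    if (length(first_times)) {
      sprintf("First-meal times: n=%d, earliest %s, median %s, latest %s",
              length(first_times), format_clock_time(min(first_times)),
              format_clock_time(as.integer(stats::median(first_times))),
              format_clock_time(max(first_times)))
    } else "First-meal times: no meals received",
    sprintf("Breastfeeding frequency distribution: %s",
            paste(sprintf("%s x%d", names(bf), as.integer(bf)),
                  collapse = ", ")),
    sprintf("Findings: %d", nrow(findings)))

  structure(list(date = date, missing_forms = missing,
                 first_meal_times = first_times,
                 top_foods_by_order = top_foods,
                 bf_frequency_distribution = bf,
                 findings = findings, text = text),
            class = "daily_report")
}

#' @export
print.daily_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Individual dietary profile for one person-day
#'
#' Per-person-day document: a timeline of meal groups with grams and
#' energy, daily nutrient totals, breastfeeding count and flags. Renders to
#' plain text deterministically and to a machine-readable JSON string.
#'
#' @param recall A `person_day_recall`.
#' @param intake The matching `person_day_intake`.
#' @return Object of class `dietary_profile` with components `timeline`
#'   (tibble), `totals`, `bf_count`, `n_unresolved`, `text` (character
#'   vector) and `json` (single JSON string).
#' @export
dietary_profile <- function(recall, intake) {
  stopifnot(inherits(recall, "person_day_recall"),
            inherits(intake, "person_day_intake"))
  d <- recall$demographics
  g <- group_meals(recall)
  e <- recall$entries
  timeline <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    ix <- sort(unlist(g$entry_indices[i]))
    rows <- e[match(ix, e$entry_index), , drop = FALSE]
    mrows <- intake$meals[match(ix, intake$meals$entry_index), ,
                          drop = FALSE]
    items <- ifelse(rows$is_breastmilk, "breast milk",
                    ifelse(nzchar(rows$description), rows$description,
                           rows$food_code))
    tibble::tibble(
      meal_order = g$meal_order[i], time = format_clock_time(g$time[i]),
      location = paste(sort(unlist(g$locations[i])), collapse = ","),
      items = paste(items, collapse = "; "),
      grams = sum(mrows$grams[!mrows$excluded]),
      energy_kcal = sum(mrows$energy_kcal[!mrows$excluded]))
  }))
  if (is.null(timeline) || nrow(timeline) == 0L) {
    timeline <- tibble::tibble(meal_order = integer(), time = character(),
                               location = character(), items = character(),
                               grams = numeric(), energy_kcal = numeric())
  }
  bf_count <- sum(e$is_breastmilk)
  text <- c(
    sprintf("Dietary profile: participant %s, %s", d$participant_id,
            as.character(d$recall_date)),
    sprintf("Meal groups: %d (breast-milk entries: %d)", nrow(g), bf_count),
    vapply(seq_len(nrow(timeline)), function(i) {
      sprintf("  %d. %s [%s] %s — %.0f g, %.0f kcal",
              timeline$meal_order[i], timeline$time[i],
              timeline$location[i], timeline$items[i], timeline$grams[i],
              timeline$energy_kcal[i])
    }, character(1)),
    sprintf("Daily totals: %.1f kcal, protein %.1f g (animal %.1f g), fat %.1f g, carb %.1f g",
            intake$totals[["energy_kcal"]], intake$totals[["protein_g"]],
            intake$totals[["animal_protein_g"]], intake$totals[["fat_g"]],
            intake$totals[["carb_g"]]),
    sprintf("Unresolved foods: %d", intake$n_unresolved))
  json <- jsonlite::toJSON(
    list(participant_id = d$participant_id,
         recall_date = as.character(d$recall_date),
         timeline = timeline, totals = as.list(intake$totals),
         bf_count = bf_count, n_unresolved = intake$n_unresolved),
    auto_unbox = TRUE, digits = NA)
  structure(list(participant_id = d$participant_id,
                 recall_date = d$recall_date, timeline = timeline,
                 totals = intake$totals, bf_count = bf_count,
                 n_unresolved = intake$n_unresolved, text = text,
                 json = as.character(json)),
            class = "dietary_profile")
}

#' @export
print.dietary_profile <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
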