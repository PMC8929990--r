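#' Group meal entries consumed at the same time
#'
#' A meal is any set of foods, snacks and beverages consumed at the same
#' time: entries whose recorded times differ by at most `tolerance_minutes`
#' are merged (single linkage on sorted times), so two food items and a
#' beverage at one sitting count as one meal. Groups are ordered by time
#' (ties broken by `entry_index`); the group time is the earliest member
#' time. The default tolerance of 0 merges identical recorded times only.
#'
#' @param recall A `person_day_recall`.
#' @param tolerance_minutes Merge window in minutes (default 0).
#' @return Tibble with one row per meal group: `meal_order` (1 = earliest),
#'   `time` (minute of day), `entry_indices` (list), `n_entries`,
#'   `locations` (list), `all_breastmilk`.
#' @export
group_meals <- function(recall, tolerance_minutes = 0) {
  stopifnot(inherits(recall, "person_day_recall"))
  e <- recall$entries
  empty <- tibble::tibble(
    meal_order = integer(), time = integer(), entry_indices = list(),
    n_entries = integer(), locations = list(), all_breastmilk = logical())
  if (nrow(e) == 0L) return(empty)
  ord <- order(e$clock_time, e$entry_index)
  e <- e[ord, , drop = FALSE]
  grp <- integer(nrow(e))
  grp[1] <- 1L
  for (i in seq_len(nrow(e))[-1]) {
    grp[i] <- if (e$clock_time[i] - e$clock_time[i - 1] > tolerance_minutes) {
      grp[i - 1] + 1L
    } else {
      grp[i - 1]
    }
  }
  ids <- unname(split(seq_len(nrow(e)), grp))
  tibble::tibble(
    meal_order = seq_along(ids),
    time = vapply(ids, function(ix) min(e$clock_time[ix]), integer(1),
                  USE.NAMES = FALSE),
    entry_indices = lapply(ids, function(ix) e$entry_index[ix]),
    n_entries = vapply(ids, length, integer(1), USE.NAMES = FALSE),
    locations = lapply(ids, function(ix) unique(e$location[ix])),
    all_breastmilk = vapply(ids, function(ix) all(e$is_breastmilk[ix]),
                            logical(1), USE.NAMES = FALSE)
  )
}

#' Meal frequency of a person-day
#'
#' Number of meal groups; breast-milk-only groups are excluded when
#' `include_breastmilk = FALSE` (mixed groups always count).
#'
#' @inheritParams group_meals
#' @param include_breastmilk Count breast-milk-only meal groups?
#' @return Integer count.
#' @export
meal_frequency <- function(recall, include_breastmilk = TRUE,
                           tolerance_minutes = 0) {
  g <- group_meals(recall, tolerance_minutes)
  if (include_breastmilk) nrow(g) else sum(!g$all_breastmilk)
}

weekday_names <- function() c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

# Locale-independent weekday label from a Date (ISO weekday number).
weekday_label <- function(date) {
  weekday_names()[as.integer(format(as.Date(date), "%u"))]
}

#' Per-meal-group energy table for one person-day
#'
#' Joins the meal grouping with a computed [personday_intake()] to one row
#' per meal group, carrying the summed energy of non-excluded members, the
#' away-from-home energy, and person-day descriptors (sex, age, weekday).
#'
#' @param recall A `person_day_recall`.
#' @param intake The matching `person_day_intake`.
#' @param tolerance_minutes Grouping tolerance, as in [group_meals()].
#' @return Tibble with columns `participant_id`, `recall_date`, `sex`,
#'   `age_value`, `age_unit`, `weekday`, `meal_order`, `time`,
#'   `energy_kcal`, `away_energy_kcal`, `n_entries`, `all_breastmilk`.
#' @export
meal_energy_table <- function(recall, intake, tolerance_minutes = 0) {
  stopifnot(inherits(recall, "person_day_recall"),
            inherits(intake, "person_day_intake"))
  g <- group_meals(recall, tolerance_minutes)
  d <- recall$demographics
  meals <- intake$meals
  energy <- vapply(g$entry_indices, function(ix) {
    rows <- meals[match(ix, meals$entry_index), , drop = FALSE]
    sum(rows$energy_kcal[!rows$excluded])
  }, numeric(1))
  away <- vapply(g$entry_indices, function(ix) {
    rows <- meals[match(ix, meals$entry_index), , drop = FALSE]
    keep <- !rows$excluded & rows$location != "home"
    sum(rows$energy_kcal[keep])
  }, numeric(1))
  tibble::tibble(
    participant_id = d$participant_id, recall_date = d$recall_date,
    sex = d$sex, age_value = d$age_value, age_unit = d$age_unit,
    weekday = weekday_label(d$recall_date),
    meal_order = g$meal_order, time = g$time,
    energy_kcal = energy, away_energy_kcal = away,
    n_entries = g$n_entries, all_breastmilk = g$all_breastmilk
  )
}

#' @rdname meal_energy_table
#' @param recalls,intakes Parallel lists of recalls and their intakes.
#' @export
cohort_meal_table <- function(recalls, intakes, tolerance_minutes = 0) {
  stopifnot(length(recalls) == length(intakes))
  dplyr::bind_rows(Map(meal_energy_table, recalls, intakes,
                       MoreArgs = list(tolerance_minutes = tolerance_minutes)))
}

#' Mean energy and energy share by meal-order position
#'
#' Summarizes a cohort meal table by stratum and meal-order position: the
#' number of person-days contributing a meal at that position, its mean
#' energy, and its share of the stratum's total energy (shares sum to 1
#' within each stratum). Meal order is the per-person-day rank by time;
#' positions are labeled 1..k rather than breakfast/lunch/dinner. Empty
#' strata are absent, not zero rows.
#'
#' @param meal_tbl Output of [cohort_meal_table()].
#' @param strata Character vector of stratifying columns (e.g. `"sex"`,
#'   `c("sex", "weekday")`); may be empty.
#' @return Tibble with the strata columns, `meal_order`, `n`,
#'   `mean_energy_kcal`, `total_energy_kcal`, `energy_share`.
#' @export
energy_by_meal_order <- function(meal_tbl, strata = "sex") {
  grouped <- dplyr::group_by(
    meal_tbl, dplyr::across(dplyr::all_of(c(strata, "meal_order"))))
  out <- dplyr::summarise(grouped, n = dplyr::n(),
                          mean_energy_kcal = mean(.data$energy_kcal),
                          total_energy_kcal = sum(.data$energy_kcal),
                          .groups = "drop")
  if (length(strata)) {
    out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(strata)))
  }
  out <- dplyr::mutate(
    out, energy_share = .data$total_energy_kcal /
      dplyr::if_else(sum(.data$total_energy_kcal) > 0,
                     sum(.data$total_energy_kcal), NA_real_))
  dplyr::arrange(dplyr::ungroup(out),
                 dplyr::across(dplyr::all_of(c(strata, "meal_order"))))
}

#' Food-away-from-home energy share of one person-day
#'
#' Energy consumed at any location other than home, divided by total daily
#' energy (breast-milk and unresolved entries excluded from both). A day
#' with zero total energy has an undefined share (`NA`), never a division
#' error.
#'
#' @param intake A `person_day_intake`.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
fafh_energy_share <- function(intake) {
  stopifnot(inherits(intake, "person_day_intake"))
  m <- intake$meals[!intake$meals$excluded, , drop = FALSE]
  total <- sum(m$energy_kcal)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  sum(m$energy_kcal[m$location != "home"]) / total
}

#' Cohort summary of food away from home
#'
#' Per-person-day shares from [fafh_energy_share()], the median share among
#' person-days with at least one away-from-home meal record (by stratum),
#' and the distribution of meal records by location in the layout of a
#' location table (counts and percent of records).
#'
#' @param recalls List of `person_day_recall`.
#' @param intakes Parallel list of `person_day_intake`.
#' @param by Demographics column to stratify by (default `"sex"`).
#' @return List with `person_days` (tibble of shares), `median_share`
#'   (tibble by stratum) and `location_distribution` (tibble by stratum and
#'   location).
#' @export
fafh_summary <- function(recalls, intakes, by = "sex") {
  stopifnot(length(recalls) == length(intakes))
  pd <- dplyr::bind_rows(Map(function(r, it) {
    d <- r$demographics
    e <- r$entries
    tibble::tibble(
      participant_id = d$participant_id, recall_date = d$recall_date,
      stratum = as.character(d[[by]]),
      share = fafh_energy_share(it),
      has_away = any(!e$is_breastmilk & e$location != "home")
    )
  }, recalls, intakes))
  med <- dplyr::summarise(
    dplyr::group_by(pd[pd$has_away & !is.na(pd$share), , drop = FALSE],
                    .data$stratum),
    n = dplyr::n(), median_share = stats::median(.data$share),
    .groups = "drop")
  loc <- dplyr::bind_rows(lapply(recalls, function(r) {
    e <- r$entries
    if (nrow(e) == 0L) return(NULL)
    tibble::tibble(stratum = as.character(r$demographics[[by]]),
                   location = e$location)
  }))
  loc_dist <- dplyr::mutate(
    dplyr::group_by(
      dplyr::count(loc, .data$stratum, .data$location, name = "records"),
      .data$stratum),
    percent = 100 * .data$records / sum(.data$records))
  list(person_days = pd, median_share = med,
       location_distribution = dplyr::ungroup(loc_dist))
}

#' Food frequency ranking across recalls
#'
#' Counts meal records per food (breast-milk entries excluded), ranked by
#' descending count with ties broken alphabetically by name; food names are
#' the entry descriptions (falling back to the food code). Optionally
#' stratified by a labeling function of the recall.
#'
#' @param recalls List of `person_day_recall`.
#' @param top_n Rows to keep per stratum (default 20).
#' @param stratifier Optional `function(recall) -> label`.
#' @return Tibble with (`stratum`,) `food`, `count`.
#' @export
food_frequency_table <- function(recalls, top_n = 20, stratifier = NULL) {
  rows <- dplyr::bind_rows(lapply(recalls, function(r) {
    e <- r$entries[!r$entries$is_breastmilk, , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    food <- ifelse(nzchar(e$description), e$description, e$food_code)
    tibble::tibble(
      stratum = if (is.null(stratifier)) "all" else as.character(stratifier(r)),
      food = food)
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble::tibble(stratum = character(), food = character(),
                          count = integer()))
  }
  counts <- dplyr::count(rows, .data$stratum, .data$food, name = "count")
  counts <- dplyr::arrange(counts, .data$stratum,
                           dplyr::desc(.data$count), .data$food)
  out <- dplyr::slice_head(dplyr::group_by(counts, .data$stratum),
                           n = top_n)
  dplyr::ungroup(out)
}

#' Histogram of meal-group timing
#'
#' Counts meal groups per half-open clock-time bin `[t, t + bin)` across
#' recalls. `bin_minutes` must divide 1440; all bins are returned, including
#' empty ones, so bin totals equal the total group count.
#'
#' @param recalls List of `person_day_recall`.
#' @param bin_minutes Bin width in minutes (default 60).
#' @param tolerance_minutes Grouping tolerance, as in [group_meals()].
#' @param include_breastmilk Include breast-milk-only groups (default
#'   `FALSE`, matching timing summaries of non-breast-milk foods)?
#' @return Tibble with `bin_start` (minute), `bin_label` (`"HH:MM"`),
#'   `count`.
#' @export
timing_histogram <- function(recalls, bin_minutes = 60,
                             tolerance_minutes = 0,
                             include_breastmilk = FALSE) {
  if (1440 %% bin_minutes != 0) {
    stop("bin_minutes must divide 1440", call. = FALSE)
  }
  times <- unlist(lapply(recalls, function(r) {
    g <- group_meals(r, tolerance_minutes)
    if (!include_breastmilk) g <- g[!g$all_breastmilk, , drop = FALSE]
    g$time
  }))
  starts <- seq(0L, 1439L, by = bin_minutes)
  counts <- vapply(starts, function(s) {
    sum(times >= s & times < s + bin_minutes)
  }, integer(1))
  tibble::tibble(bin_start = starts, bin_label = format_clock_time(starts),
                 count = counts)
}

#' Recover meal-timing modes from grouped times
#'
#' Kernel-density mode estimator used to check that a cohort's meal-timing
#' mixture is recovered: the `k` highest local density maxima separated by
#' at least `min_separation` minutes, in clock order.
#'
#' @param times Numeric vector of meal-group times (minutes of day).
#' @param k Number of modes to return.
#' @param bw Kernel bandwidth in minutes.
#' @param min_separation Minimum spacing between reported modes.
#' @return Numeric vector of length at most `k` (minutes of day).
#' @export
recover_timing_modes <- function(times, k = 3, bw = 25,
                                 min_separation = 120) {
  stopifnot(length(times) > k)
  d <- stats::density(times, bw = bw, from = 0, to = 1439, n = 1024)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1L
  peak <- peak[order(y[peak], decreasing = TRUE)]
  chosen <- numeric(0)
  for (p in peak) {
    if (length(chosen) >= k) break
    if (all(abs(d$x[p] - chosen) >= min_separation)) {
      chosen <- c(chosen, d$x[p])
    }
  }
  sort(chosen)
}
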