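#' Quality-control configuration
#'
#' Thresholds for the interview-review rules. `max_gap_minutes` flags long
#' gaps between consecutive meal groups; `morning_cutoff` (minute of day,
#' default 600 = 10:00) defines "morning" for the two-mornings heuristic;
#' `portion_max_g` caps plausible grams per meal entry by age class
#' (infant < 24 months, child < 18 years, adult); `availability` is an
#' optional vector of food codes available in the study region.
#'
#' @param max_gap_minutes Gap threshold in minutes (default 360).
#' @param morning_cutoff Morning boundary in minutes (default 600).
#' @param portion_max_g Named numeric, `c(infant=, child=, adult=)` grams.
#' @param availability Optional character vector of available food codes.
#' @param meal_tolerance_minutes Grouping tolerance for gap checks.
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(max_gap_minutes = 360, morning_cutoff = 600,
                      portion_max_g = c(infant = 800, child = 1500,
                                        adult = 3500),
                      availability = NULL, meal_tolerance_minutes = 0) {
  stopifnot(max_gap_minutes > 0, morning_cutoff > 0,
            all(portion_max_g > 0),
            all(c("infant", "child", "adult") %in% names(portion_max_g)))
  structure(list(max_gap_minutes = max_gap_minutes,
                 morning_cutoff = morning_cutoff,
                 portion_max_g = portion_max_g,
                 availability = availability,
                 meal_tolerance_minutes = meal_tolerance_minutes),
            class = "qc_config")
}

qc_rule_ids <- function() {
  c("BF_MISMATCH", "TWO_MORNINGS", "TIME_GAP", "IMPLAUSIBLE_PORTION",
    "UNAVAILABLE_FOOD")
}

new_finding <- function(rule_id, severity, message, entry_refs = integer()) {
  stopifnot(rule_id %in% qc_rule_ids(), severity %in% c("error", "warning"))
  tibble::tibble(rule_id = rule_id, severity = severity, message = message,
                 entry_refs = list(as.integer(entry_refs)))
}

empty_findings <- function() {
  tibble::tibble(rule_id = character(), severity = character(),
                 message = character(), entry_refs = list())
}

# Age class for portion plausibility: infant < 24 mo, child < 18 y, adult.
age_class <- function(age_value, age_unit) {
  months <- if (age_unit == "months") age_value else age_value * 12
  if (months < 24) "infant" else if (months < 216) "child" else "adult"
}

#' Apply the interview quality-control rules to one recall
#'
#' Emits findings, independently per rule:
#' \describe{
#'   \item{BF_MISMATCH (error)}{the number of breast-milk meal entries does
#'     not equal the declared breastfeeding frequency — the frequency
#'     declared at the start of the interview must match the breastfeeding
#'     meals entered.}
#'   \item{TWO_MORNINGS (warning)}{heuristic for a recall spanning two
#'     mornings (e.g. 08:00 yesterday to 08:00 today): entry times in
#'     recorded order decrease at some point, and both the pre- and
#'     post-decrease segments contain a time before `morning_cutoff`.}
#'   \item{TIME_GAP (warning)}{one finding per gap between consecutive meal
#'     groups exceeding `max_gap_minutes`.}
#'   \item{IMPLAUSIBLE_PORTION (warning)}{converted grams of an entry
#'     exceed the age-class threshold (requires `db`; entries whose portion
#'     key cannot be matched are skipped here).}
#'   \item{UNAVAILABLE_FOOD (warning)}{the food code is outside
#'     `cfg$availability`, when a regional availability list is provided.}
#' }
#' A clean recall yields an empty finding table. Findings depend only on
#' `entry_index` order, never on file row order.
#'
#' @param recall A `person_day_recall`.
#' @param cfg A [qc_config()].
#' @param db Optional `portion_db` enabling the portion-plausibility rule.
#' @param ctx Optional [fct_context()] (or `fct_table`) used to find food
#'   groups for group-level portion lookup.
#' @return Tibble of findings: `rule_id`, `severity`, `message`,
#'   `entry_refs` (list of entry indices).
#' @export
validate_recall <- function(recall, cfg = qc_config(), db = NULL,
                            ctx = NULL) {
  stopifnot(inherits(recall, "person_day_recall"),
            inherits(cfg, "qc_config"))
  d <- recall$demographics
  e <- recall$entries
  e <- e[order(e$entry_index), , drop = FALSE]
  findings <- list()

  declared <- d$declared_bf_frequency
  if (!is.na(declared)) {
    n_bf <- sum(e$is_breastmilk)
    if (n_bf != declared) {
      findings <- c(findings, list(new_finding(
        "BF_MISMATCH", "error",
        sprintf("declared breastfeeding frequency %d but %d breast-milk entries recorded",
                declared, n_bf),
        e$entry_index[e$is_breastmilk])))
    }
  }

  if (nrow(e) >= 2L) {
    tt <- e$clock_time
    dec <- which(diff(tt) < 0)
    for (k in dec) {
      pre <- tt[seq_len(k)]
      post <- tt[(k + 1):length(tt)]
      if (any(pre < cfg$morning_cutoff) && any(post < cfg$morning_cutoff)) {
        findings <- c(findings, list(new_finding(
          "TWO_MORNINGS", "warning",
          sprintf("entry times fall back from %s to %s with morning times on both sides; recall may span two mornings",
                  format_clock_time(tt[k]), format_clock_time(tt[k + 1])),
          e$entry_index[c(k, k + 1)])))
        break
      }
    }
  }

  groups <- group_meals(recall, cfg$meal_tolerance_minutes)
  if (nrow(groups) >= 2L) {
    gaps <- diff(groups$time)
    for (k in which(gaps > cfg$max_gap_minutes)) {
      findings <- c(findings, list(new_finding(
        "TIME_GAP", "warning",
        sprintf("%d-minute gap between meals at %s and %s exceeds %d minutes",
                gaps[k], format_clock_time(groups$time[k]),
                format_clock_time(groups$time[k + 1]),
                cfg$max_gap_minutes),
        unlist(groups$entry_indices[c(k, k + 1)]))))
    }
  }

  if (!is.null(db)) {
    threshold <- cfg$portion_max_g[[age_class(d$age_value, d$age_unit)]]
    primary <- if (inherits(ctx, "fct_context")) ctx$primary else ctx
    for (i in which(!e$is_breastmilk)) {
      item <- fct_lookup(primary, e$food_code[i])
      grp <- if (is.null(item)) NULL else item$food_group[1]
      conv <- tryCatch(
        amount_consumed_g(e[i, , drop = FALSE], db, food_group = grp),
        error = function(cnd) NULL)
      if (!is.null(conv) && conv$grams > threshold) {
        findings <- c(findings, list(new_finding(
          "IMPLAUSIBLE_PORTION", "warning",
          sprintf("entry %d: %.0f g exceeds the %s plausibility threshold of %.0f g",
                  e$entry_index[i], conv$grams,
                  age_class(d$age_value, d$age_unit), threshold),
          e$entry_index[i])))
      }
    }
  }

  if (!is.null(cfg$availability)) {
    for (i in which(!e$is_breastmilk)) {
      code <- e$food_code[i]
      if (nzchar(code) && !code %in% sentinel_codes() &&
          !code %in% cfg$availability) {
        findings <- c(findings, list(new_finding(
          "UNAVAILABLE_FOOD", "warning",
          sprintf("entry %d: food %s (%s) is outside the regional availability list",
                  e$entry_index[i], code, e$description[i]),
          e$entry_index[i])))
      }
    }
  }

  if (length(findings) == 0L) return(empty_findings())
  dplyr::bind_rows(findings)
}
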