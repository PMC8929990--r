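#' Reference utensils
#'
#' The seven reference serving-size utensils used as interview aids, each
#' reported in three size classes.
#'
#' @return Tibble with columns `utensil` and `sizes` (list column).
#' @export
utensil_registry <- function() {
  tibble::tibble(
    utensil = c("bowl", "cup", "tumbler", "plate", "tablespoon", "teaspoon",
                "saucer"),
    sizes = rep(list(c("small", "medium", "large")), 7)
  )
}

portion_key <- function(code_or_group, utensil, size) {
  paste(code_or_group, utensil, size, sep = "|")
}

#' Construct a portion-size database
#'
#' Maps `(food code or food group, utensil, size)` to grams per serving
#' unit. Food-specific entries take precedence over food-group defaults;
#' gram weights bake in the density of the food as served, so no volumetric
#' modeling is needed. Keys must be unique and gram weights positive.
#'
#' @param entries Tibble with columns `food_code_or_group`, `utensil`,
#'   `size`, `grams_per_unit` and optionally `provenance`.
#' @return Object of class `portion_db`.
#' @export
portion_db <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("food_code_or_group", "utensil", "size", "grams_per_unit")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("portion database is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(entries$provenance)) entries$provenance <- ""
  entries <- entries[, c(required, "provenance")]
  for (col in c("food_code_or_group", "utensil", "size", "provenance")) {
    entries[[col]] <- as.character(entries[[col]])
  }
  entries$grams_per_unit <- as.numeric(entries$grams_per_unit)
  if (anyNA(entries$grams_per_unit) || any(entries$grams_per_unit <= 0)) {
    stop("grams_per_unit must be > 0 for every portion entry", call. = FALSE)
  }
  keys <- portion_key(entries$food_code_or_group, entries$utensil,
                      entries$size)
  if (anyDuplicated(keys)) {
    stop("duplicate portion key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = entries), class = "portion_db")
}

#' @export
print.portion_db <- function(x, ...) {
  cat(sprintf("<portion_db: %d entries>\n", nrow(x$entries)))
  invisible(x)
}

#' Load a portion-size database from delimited text
#'
#' Columns: `food_code_or_group`, `utensil`, `size`, `grams_per_unit`,
#' `provenance`. Nonpositive gram weights and duplicate keys are errors.
#'
#' @param path File path (comma default, tab accepted).
#' @param delim Delimiter override.
#' @return A `portion_db`.
#' @export
load_portion_db <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = sniff_delim(path, delim), show_col_types = FALSE,
    progress = FALSE,
    col_types = readr::cols(food_code_or_group = readr::col_character(),
                            .default = readr::col_guess())
  )
  portion_db(raw)
}

#' @rdname load_portion_db
#' @param db A `portion_db`.
#' @export
write_portion_db <- function(db, path) {
  stopifnot(inherits(db, "portion_db"))
  readr::write_csv(db$entries, path, progress = FALSE)
  invisible(path)
}

#' Convert a portion report to grams consumed
#'
#' Looks up grams per unit for the entry's `(food_code, utensil,
#' utensil_size)` key, falling back to the `(food_group, utensil, size)`
#' default when no food-specific entry exists, and multiplies by
#' `portion_count`. The matched key and precedence level are returned for
#' audit. Breast-milk entries carry no quantity and are a contract
#' violation here.
#'
#' @param entry One meal entry (one-row tibble or list with `food_code`,
#'   `utensil`, `utensil_size`, `portion_count`, `is_breastmilk`).
#' @param db A `portion_db`.
#' @param food_group Food group of the entry's food, used for the fallback
#'   level; lookup is food-specific only when `NULL`.
#' @param fallback_g Optional grams per unit used (with a warning) when
#'   neither level matches; by default a missing mapping is an error naming
#'   the key.
#' @return List with `grams`, `grams_per_unit`, `level` (`"food"`,
#'   `"group"` or `"fallback"`) and `key`.
#' @export
amount_consumed_g <- function(entry, db, food_group = NULL,
                              fallback_g = NULL) {
  stopifnot(inherits(db, "portion_db"))
  if (isTRUE(entry$is_breastmilk[[1]])) {
    stop("breast-milk entries carry timing and location only; ",
         "no gram amount is defined", call. = FALSE)
  }
  pc <- as.numeric(entry$portion_count[[1]])
  if (is.na(pc) || pc <= 0) {
    stop("portion_count must be > 0", call. = FALSE)
  }
  e <- db$entries
  u <- as.character(entry$utensil[[1]])
  s <- as.character(entry$utensil_size[[1]])
  code <- as.character(entry$food_code[[1]])

  hit <- which(e$food_code_or_group == code & e$utensil == u & e$size == s)
  if (length(hit)) {
    gpu <- e$grams_per_unit[hit[1]]
    return(list(grams = pc * gpu, grams_per_unit = gpu, level = "food",
                key = portion_key(code, u, s)))
  }
  if (!is.null(food_group)) {
    hit <- which(e$food_code_or_group == food_group & e$utensil == u &
                   e$size == s)
    if (length(hit)) {
      gpu <- e$grams_per_unit[hit[1]]
      return(list(grams = pc * gpu, grams_per_unit = gpu, level = "group",
                  key = portion_key(food_group, u, s)))
    }
  }
  key <- portion_key(code, u, s)
  if (!is.null(fallback_g)) {
    warning("no portion entry for ", key, "; using fallback ", fallback_g,
            " g/unit", call. = FALSE)
    return(list(grams = pc * fallback_g, grams_per_unit = fallback_g,
                level = "fallback", key = key))
  }
  stop("no food-specific or group-level portion entry for key ", key,
       call. = FALSE)
}
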