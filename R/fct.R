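#' Sentinel food codes
#'
#' Two codes are reserved in the export: `"9999"` marks an unknown meal (not
#' in the primary food-composition table, to be assigned post hoc) and
#' `"8888"` marks a meal recorded as a new recipe. Neither may appear as a
#' food code inside a food-composition table.
#'
#' @return Named character vector with elements `unknown` and `new_recipe`.
#' @export
sentinel_codes <- function() {
  c(unknown = "9999", new_recipe = "8888")
}

UNKNOWN_CODE <- "9999"
NEW_RECIPE_CODE <- "8888"

fct_required_columns <- function() c("code", "name", "food_group", "edible_fraction")

#' Construct a food-composition table
#'
#' Normally produced by [load_fct()] or [generate_fct()]; exposed so mock
#' tables can be built in code. Per-100 g values refer to 100 g of edible
#' portion; `edible_fraction` is the consumable fraction of as-served weight.
#'
#' @param items Tibble with columns `code`, `name`, `food_group`,
#'   `edible_fraction` and the eleven [nutrient_names()] columns.
#' @param source_label `"primary"`, `"secondary"` or another short label.
#' @return An object of class `fct_table`.
#' @export
fct_table <- function(items, source_label = "primary") {
  items <- tibble::as_tibble(items)
  missing_req <- setdiff(fct_required_columns(), names(items))
  if (length(missing_req)) {
    stop("food-composition table is missing column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  missing_nut <- setdiff(nutrient_names(), names(items))
  if (length(missing_nut)) {
    stop("food-composition table is missing nutrient column(s): ",
         paste(missing_nut, collapse = ", "), call. = FALSE)
  }
  items <- items[, c(fct_required_columns(), nutrient_names())]
  items$code <- as.character(items$code)
  items$edible_fraction <- as.numeric(items$edible_fraction)
  for (nm in nutrient_names()) items[[nm]] <- as.numeric(items[[nm]])

  if (any(!nzchar(items$code)) || anyNA(items$code)) {
    stop("food codes must be nonempty", call. = FALSE)
  }
  sent <- items$code %in% sentinel_codes()
  if (any(sent)) {
    stop("sentinel code(s) used as food code: ",
         paste(unique(items$code[sent]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(items$code)) {
    dup <- unique(items$code[duplicated(items$code)])
    rows <- vapply(dup, function(cd) {
      paste(which(items$code == cd), collapse = " and ")
    }, character(1))
    stop("duplicate food code(s): ",
         paste(sprintf("%s (rows %s)", dup, rows), collapse = "; "),
         call. = FALSE)
  }
  if (nrow(items)) {
    if (anyNA(items$edible_fraction) ||
        any(items$edible_fraction <= 0 | items$edible_fraction > 1)) {
      stop("edible_fraction must lie in (0, 1]", call. = FALSE)
    }
    nut <- as.matrix(items[, nutrient_names()])
    if (anyNA(nut)) stop("nutrient values contain NA", call. = FALSE)
    if (any(nut < 0)) {
      bad <- which(apply(nut < 0, 1, any))
      stop("negative nutrient value(s) in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ap_over <- items$animal_protein_g > items$protein_g + 1e-9
    if (any(ap_over)) {
      stop("animal_protein_g exceeds protein_g in row(s): ",
           paste(which(ap_over), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(source_label = source_label, items = items),
            class = "fct_table")
}

#' @export
print.fct_table <- function(x, ...) {
  cat(sprintf("<fct_table '%s': %d food item(s), %d food group(s)>\n",
              x$source_label, nrow(x$items),
              length(unique(x$items$food_group))))
  invisible(x)
}

sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) && grepl("\t", header)) "\t" else ","
}

#' Load a food-composition table from a delimited file
#'
#' Reads a UTF-8 delimited file (comma default, tab accepted) whose header
#' names `code`, `name`, `food_group`, `edible_fraction` and then nutrient
#' columns by their canonical [nutrient_names()]. Nutrient columns missing
#' from the file are filled with 0 and a warning is issued. Duplicate codes,
#' sentinel codes and negative nutrient values are errors.
#'
#' @param path File path.
#' @param source_label Label recorded on the table, `"primary"` by default.
#' @param delim Field delimiter; sniffed from the header when `NULL`.
#' @return An `fct_table`.
#' @export
load_fct <- function(path, source_label = "primary", delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path, delim)
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(code = readr::col_character())
  )
  missing_req <- setdiff(fct_required_columns(), names(raw))
  if (length(missing_req)) {
    stop("FCT file ", path, " is missing column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  missing_nut <- setdiff(nutrient_names(), names(raw))
  if (length(missing_nut)) {
    warning("FCT file ", path, ": nutrient column(s) missing, defaulting to 0: ",
            paste(missing_nut, collapse = ", "), call. = FALSE)
    for (nm in missing_nut) raw[[nm]] <- 0
  }
  if (nrow(raw) == 0L) {
    raw$code <- character(0)
    raw$edible_fraction <- numeric(0)
  }
  fct_table(raw, source_label = source_label)
}

#' Write a food-composition table back to delimited text
#'
#' Inverse of [load_fct()]: re-reading the written file reproduces all items.
#'
#' @param fct An `fct_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fct <- function(fct, path) {
  stopifnot(inherits(fct, "fct_table"))
  readr::write_csv(fct$items, path, progress = FALSE)
  invisible(path)
}

#' Look up a food item by code
#'
#' @param fct An `fct_table` (or `NULL`, in which case no match).
#' @param code Food code.
#' @return One-row tibble, or `NULL` when absent.
#' @export
fct_lookup <- function(fct, code) {
  if (is.null(fct)) return(NULL)
  stopifnot(inherits(fct, "fct_table"))
  hit <- fct$items[fct$items$code == as.character(code), , drop = FALSE]
  if (nrow(hit) == 0L) NULL else hit[1, , drop = FALSE]
}
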