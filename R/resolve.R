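resolved_food <- function(source, item = NULL, audit = character()) {
  if (source == "unresolved" && !is.null(item)) {
    stop("unresolved foods carry no item", call. = FALSE)
  }
  if (source != "unresolved" && is.null(item)) {
    stop("resolved foods must carry an item", call. = FALSE)
  }
  structure(list(source = source, item = item,
                 audit = paste(audit, collapse = "; ")),
            class = "resolved_food")
}

#' @export
print.resolved_food <- function(x, ...) {
  nm <- if (is.null(x$item)) "-" else x$item$name[1]
  cat(sprintf("<resolved_food %s: %s [%s]>\n", x$source, nm, x$audit))
  invisible(x)
}

# Pseudo food item derived from a recipe's per-100 g vector.
recipe_item <- function(rec, per100) {
  tibble::tibble(
    code = rec$recipe_id, name = rec$description,
    food_group = "recipe", edible_fraction = 1,
    !!!as.list(per100)
  )
}

#' Load a code-assignment table
#'
#' Assignments record the outcome of the manual review of unknown meals: a
#' YAML mapping from an entry id (`"participant|date|index"`) or a meal
#' description to either a food code (primary or secondary table) or a
#' registered recipe id. The file is a reviewable artifact; no fuzzy text
#' matching is performed.
#'
#' @param path YAML file path.
#' @return Named list of character targets (empty list for an empty file).
#' @export
load_assignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(list())
  lapply(raw, as.character)
}

#' @rdname load_assignments
#' @param assignments Named list mapping entry ids or descriptions to codes.
#' @export
save_assignments <- function(assignments, path) {
  yaml::write_yaml(assignments, path)
  invisible(path)
}

#' Resolve a food code through the assignment cascade
#'
#' Deterministic cascade mirroring the post-collection review workflow:
#' \enumerate{
#'   \item the code is found in the primary table: `source = "primary_fct"`;
#'   \item the code is the unknown sentinel (`"9999"`) and the assignment
#'     table maps this entry (by entry id, else by description) to a primary
#'     or secondary code, or to a registered recipe;
#'   \item the code is the new-recipe sentinel (`"8888"`) and the assignment
#'     table maps this entry to a registered recipe, whose per-100 g vector
#'     is computed with [recipe_nutrients_per_100g()];
#'   \item otherwise `source = "unresolved"`.
#' }
#' A new-recipe code with no recipe assigned yields `unresolved` with a
#' distinct audit message, not an error. The audit field records the
#' resolution path taken.
#'
#' @param code Food code or sentinel, as recorded.
#' @param description Free-text meal description (assignment fallback key).
#' @param primary,secondary `fct_table`s; `secondary` may be `NULL`.
#' @param assignments Named list from [load_assignments()]; may be empty.
#' @param recipes A [recipe_registry()] or `NULL`.
#' @param entry_id Entry identifier used as the preferred assignment key.
#' @return Object of class `resolved_food` with fields `source`
#'   (`primary_fct`, `secondary_fct`, `recipe` or `unresolved`), `item`
#'   (one-row food-item tibble, present iff resolved) and `audit`.
#' @export
resolve_code <- function(code, description = NULL, primary, secondary = NULL,
                         assignments = list(), recipes = NULL,
                         entry_id = NULL) {
  stopifnot(inherits(primary, "fct_table"))
  code <- as.character(code)
  audit <- character()

  if (!code %in% sentinel_codes() && nzchar(code)) {
    hit <- fct_lookup(primary, code)
    if (!is.null(hit)) {
      return(resolved_food("primary_fct", hit,
                           sprintf("code %s found in primary FCT", code)))
    }
    audit <- c(audit, sprintf("code %s not found in primary FCT", code))
  }

  target <- NULL
  key_used <- NULL
  if (!is.null(entry_id) && !is.null(assignments[[entry_id]])) {
    target <- as.character(assignments[[entry_id]])
    key_used <- paste0("entry id ", entry_id)
  } else if (!is.null(description) && nzchar(description %||% "") &&
             !is.null(assignments[[description]])) {
    target <- as.character(assignments[[description]])
    key_used <- paste0("description '", description, "'")
  }

  lookup_recipe <- function(id) {
    if (is.null(recipes)) return(NULL)
    recipes$recipes[[id]]
  }

  if (code == UNKNOWN_CODE) {
    if (is.null(target)) {
      return(resolved_food("unresolved", NULL,
                           c(audit, "unknown code 9999 with no assignment")))
    }
    audit <- c(audit, sprintf("assignment via %s -> %s", key_used, target))
    rec <- lookup_recipe(target)
    if (!is.null(rec)) {
      per100 <- recipe_nutrients_per_100g(
        rec, Filter(Negate(is.null), list(primary, secondary)))
      return(resolved_food("recipe", recipe_item(rec, per100),
                           c(audit, sprintf("recipe %s", target))))
    }
    hit <- fct_lookup(primary, target)
    if (!is.null(hit)) {
      return(resolved_food("primary_fct", hit,
                           c(audit, "assigned code found in primary FCT")))
    }
    hit <- fct_lookup(secondary, target)
    if (!is.null(hit)) {
      return(resolved_food("secondary_fct", hit,
                           c(audit, "assigned code found in secondary FCT")))
    }
    return(resolved_food("unresolved", NULL,
                         c(audit, sprintf("assignment target %s not found",
                                          target))))
  }

  if (code == NEW_RECIPE_CODE) {
    if (!is.null(target)) {
      rec <- lookup_recipe(target)
      if (!is.null(rec)) {
        per100 <- recipe_nutrients_per_100g(
          rec, Filter(Negate(is.null), list(primary, secondary)))
        return(resolved_food(
          "recipe", recipe_item(rec, per100),
          c(audit, sprintf("assignment via %s -> recipe %s",
                           key_used, target))))
      }
      return(resolved_food(
        "unresolved", NULL,
        c(audit, sprintf("new-recipe code 8888: assigned recipe %s not registered",
                         target))))
    }
    return(resolved_food(
      "unresolved", NULL,
      c(audit, "new-recipe code 8888 with no recipe assigned")))
  }

  resolved_food("unresolved", NULL,
                c(audit, "cascade exhausted"))
}
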