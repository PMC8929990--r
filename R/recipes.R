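#' Define a recipe
#'
#' A recipe records the ingredients (food codes and raw grams) of a meal that
#' has no code in the reference tables, optionally with the cooked weight of
#' the prepared dish. Recipe identifiers live in their own namespace,
#' separate from food codes.
#'
#' @param recipe_id Identifier, nonempty.
#' @param description Free-text description of the dish.
#' @param ingredients Data frame with columns `code` (food code resolvable in
#'   a food-composition table) and `grams` (raw ingredient mass, > 0). At
#'   least one ingredient.
#' @param cooked_weight_g Optional cooked weight of the whole dish in grams
#'   (> 0). When absent, the raw ingredient total is used as the yield.
#' @param method_notes,source_doc Free-text notes on preparation and the
#'   documentation source of the recipe.
#' @return Object of class `recipe`.
#' @export
#' @examples
#' recipe("R001", "maize porridge",
#'        data.frame(code = c("T001", "T030"), grams = c(80, 400)),
#'        cooked_weight_g = 450)
recipe <- function(recipe_id, description, ingredients,
                   cooked_weight_g = NULL, method_notes = "",
                   source_doc = "") {
  stopifnot(is.character(recipe_id), length(recipe_id) == 1L,
            nzchar(recipe_id))
  ingredients <- tibble::as_tibble(ingredients)
  if (!all(c("code", "grams") %in% names(ingredients))) {
    stop("ingredients need columns 'code' and 'grams'", call. = FALSE)
  }
  ingredients$code <- as.character(ingredients$code)
  ingredients$grams <- as.numeric(ingredients$grams)
  if (nrow(ingredients) < 1L) {
    stop("recipe '", recipe_id, "' needs at least one ingredient",
         call. = FALSE)
  }
  if (anyNA(ingredients$grams) || any(ingredients$grams <= 0)) {
    stop("all ingredient masses must be > 0", call. = FALSE)
  }
  if (!is.null(cooked_weight_g)) {
    cooked_weight_g <- as.numeric(cooked_weight_g)
    if (is.na(cooked_weight_g) || cooked_weight_g <= 0) {
      stop("cooked_weight_g must be > 0 when given", call. = FALSE)
    }
  }
  structure(
    list(recipe_id = recipe_id,
         description = as.character(description),
         ingredients = ingredients[, c("code", "grams")],
         cooked_weight_g = cooked_weight_g,
         method_notes = as.character(method_notes),
         source_doc = as.character(source_doc)),
    class = "recipe"
  )
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("<recipe %s: %s; %d ingredient(s), yield %s g>\n",
              x$recipe_id, x$description, nrow(x$ingredients),
              if (is.null(x$cooked_weight_g)) "raw-mass"
              else format(x$cooked_weight_g)))
  invisible(x)
}

#' Recipe registries
#'
#' A registry is a keyed collection of [recipe()] objects that persists to a
#' human-editable YAML file. `register_recipe()` refuses duplicate ids;
#' `save_recipe_registry()` / `load_recipe_registry()` round-trip all fields.
#'
#' @param recipes Optional list of `recipe` objects to seed the registry.
#' @return `recipe_registry()` and `register_recipe()` return the registry;
#'   `load_recipe_registry()` returns a registry read from `path`.
#' @export
recipe_registry <- function(recipes = list()) {
  reg <- structure(list(recipes = list()), class = "recipe_registry")
  for (r in recipes) reg <- register_recipe(r, reg)
  reg
}

#' @rdname recipe_registry
#' @param rec A `recipe`.
#' @param registry A `recipe_registry`.
#' @export
register_recipe <- function(rec, registry) {
  stopifnot(inherits(rec, "recipe"), inherits(registry, "recipe_registry"))
  if (rec$recipe_id %in% names(registry$recipes)) {
    stop("recipe id already registered: ", rec$recipe_id, call. = FALSE)
  }
  registry$recipes[[rec$recipe_id]] <- rec
  registry
}

#' @rdname recipe_registry
#' @param path YAML file path.
#' @export
save_recipe_registry <- function(registry, path) {
  stopifnot(inherits(registry, "recipe_registry"))
  out <- lapply(registry$recipes, function(r) {
    list(recipe_id = r$recipe_id,
         description = r$description,
         ingredients = lapply(seq_len(nrow(r$ingredients)), function(i) {
           list(code = r$ingredients$code[i],
                grams = r$ingredients$grams[i])
         }),
         cooked_weight_g = r$cooked_weight_g,
         method_notes = r$method_notes,
         source_doc = r$source_doc)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname recipe_registry
#' @export
load_recipe_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  recs <- lapply(raw, function(r) {
    ing <- tibble::tibble(
      code = vapply(r$ingredients, function(x) as.character(x$code),
                    character(1)),
      grams = vapply(r$ingredients, function(x) as.numeric(x$grams),
                     numeric(1))
    )
    recipe(r$recipe_id, r$description, ing,
           cooked_weight_g = r$cooked_weight_g,
           method_notes = r$method_notes %||% "",
           source_doc = r$source_doc %||% "")
  })
  recipe_registry(recs)
}

#' @export
print.recipe_registry <- function(x, ...) {
  cat(sprintf("<recipe_registry: %d recipe(s)>\n", length(x$recipes)))
  invisible(x)
}

#' Compute recipe nutrients per 100 g
#'
#' Each ingredient contributes `grams * edible_fraction * per100g / 100`
#' componentwise; the total is renormalized to 100 g of the cooked weight
#' when recorded, otherwise of the raw ingredient mass. No nutrient
#' retention factors are applied: locally specific factors are typically
#' unavailable, and the resulting per-100 g vector is a raw-composition
#' estimate of the prepared dish.
#'
#' When the cooked weight is absent a message notes that the moisture change
#' of cooking is ignored.
#'
#' @param rec A [recipe()].
#' @param tables An `fct_table`, or a list of them searched in order
#'   (e.g. primary, secondary, supplemental).
#' @return Nutrient vector per 100 g of prepared dish.
#' @export
recipe_nutrients_per_100g <- function(rec, tables) {
  stopifnot(inherits(rec, "recipe"))
  if (inherits(tables, "fct_table")) tables <- list(tables)
  total <- nv_zero()
  for (i in seq_len(nrow(rec$ingredients))) {
    code <- rec$ingredients$code[i]
    grams <- rec$ingredients$grams[i]
    item <- NULL
    for (tb in tables) {
      item <- fct_lookup(tb, code)
      if (!is.null(item)) break
    }
    if (is.null(item)) {
      stop("recipe '", rec$recipe_id,
           "': ingredient not resolvable in any table: ", code,
           call. = FALSE)
    }
    total <- total +
      grams * item$edible_fraction[1] * item_nutrients(item) / 100
  }
  yield <- rec$cooked_weight_g
  if (is.null(yield)) {
    yield <- sum(rec$ingredients$grams)
    message("recipe '", rec$recipe_id, "': no cooked weight recorded; ",
            "using raw ingredient mass as yield (moisture change ignored)")
  }
  if (yield <= 0) {
    stop("recipe '", rec$recipe_id, "': yield must be > 0", call. = FALSE)
  }
  validate_nutrient_vector(100 * total / yield,
                           where = paste0("recipe ", rec$recipe_id))
}
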