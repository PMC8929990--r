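#' Canonical nutrient component names
#'
#' The eleven nutrients tracked throughout the package, in canonical order:
#' energy (kcal), protein (g), animal-source protein (g), fat (g),
#' carbohydrate (g), fiber (file unit, see [fiber_unit()]), calcium (mg),
#' iron (mg), zinc (mg), vitamin A (ug retinol equivalents) and folate (ug).
#' Food-composition files, recipe outputs and intake tables all use these
#' column names.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' nutrient_names()
nutrient_names <- function() {
  c("energy_kcal", "protein_g", "animal_protein_g", "fat_g", "carb_g",
    "fiber", "calcium_mg", "iron_mg", "zinc_mg", "vitA_ug_RE", "folate_ug")
}

#' Fiber unit label
#'
#' Fiber is carried in whatever unit the food-composition file reports; the
#' label is metadata, never converted. The default matches the label used in
#' the bundled summaries ("mg").
#'
#' @param unit Optional new label; when supplied it is set for the session.
#' @return The current fiber unit label, invisibly when setting.
#' @export
fiber_unit <- function(unit = NULL) {
  if (is.null(unit)) {
    return(getOption("recall24.fiber_unit", "mg"))
  }
  stopifnot(is.character(unit), length(unit) == 1L)
  options(recall24.fiber_unit = unit)
  invisible(unit)
}

#' Construct a nutrient vector
#'
#' A nutrient vector is a named numeric vector over [nutrient_names()],
#' non-negative componentwise, with animal-source protein bounded by total
#' protein. Addition and scalar scaling are the ordinary componentwise
#' operations on named numerics.
#'
#' @param ... Named components (e.g. `energy_kcal = 120`); unnamed components
#'   are not accepted. Omitted components default to 0.
#' @param .values Alternatively, a named numeric vector of components.
#' @return Named numeric vector of length 11.
#' @export
#' @examples
#' nutrient_vector(energy_kcal = 365, protein_g = 7.5, carb_g = 79)
nutrient_vector <- function(..., .values = NULL) {
  vals <- if (is.null(.values)) c(...) else .values
  out <- nv_zero()
  if (length(vals)) {
    if (is.null(names(vals)) || any(names(vals) == "")) {
      stop("all nutrient components must be named", call. = FALSE)
    }
    bad <- setdiff(names(vals), nutrient_names())
    if (length(bad)) {
      stop("unknown nutrient component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out[names(vals)] <- as.numeric(vals)
  }
  validate_nutrient_vector(out)
}

#' @rdname nutrient_vector
#' @export
nv_zero <- function() {
  stats::setNames(numeric(length(nutrient_names())), nutrient_names())
}

#' Validate a nutrient vector
#'
#' Checks names, non-negativity and the animal-protein bound.
#'
#' @param nv Named numeric vector over [nutrient_names()].
#' @param where Optional context string used in error messages.
#' @return `nv`, invisibly usable, after validation.
#' @export
validate_nutrient_vector <- function(nv, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  if (!identical(names(nv), nutrient_names())) {
    stop("nutrient vector must be named by nutrient_names()", ctx,
         call. = FALSE)
  }
  if (anyNA(nv)) stop("nutrient vector contains NA", ctx, call. = FALSE)
  if (any(nv < 0)) {
    stop("nutrient components must be >= 0: ",
         paste(names(nv)[nv < 0], collapse = ", "), ctx, call. = FALSE)
  }
  if (nv[["animal_protein_g"]] > nv[["protein_g"]] + 1e-9) {
    stop("animal_protein_g exceeds protein_g", ctx, call. = FALSE)
  }
  nv
}

# Extract the nutrient vector from a one-row food-item tibble.
item_nutrients <- function(item_row) {
  out <- as.numeric(item_row[1, nutrient_names()])
  stats::setNames(out, nutrient_names())
}
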