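# Independent brute-force recomputation of person-day nutrient totals from
# the raw export files, written against base R only (read.csv, data-frame
# subsetting, explicit loops). Deliberately shares no code with the package
# computation path.

oracle_personday_totals <- function(demog_path, meals_path, fct_paths,
                                    portion_path, assignments = list()) {
  d <- utils::read.csv(demog_path, colClasses = "character")
  m <- utils::read.csv(meals_path, colClasses = "character")
  fct <- do.call(rbind, lapply(fct_paths, utils::read.csv,
                               colClasses = "character"))
  pdb <- utils::read.csv(portion_path, colClasses = "character")
  nuts <- nutrient_names()
  out <- matrix(0, nrow = nrow(d), ncol = length(nuts),
                dimnames = list(paste(d$participant_id, d$recall_date,
                                      sep = "|"), nuts))
  for (i in seq_len(nrow(d))) {
    rows <- m[m$participant_id == d$participant_id[i] &
                m$recall_date == d$recall_date[i], , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      if (toupper(rows$is_breastmilk[j]) == "TRUE") next
      code <- rows$food_code[j]
      if (code == "9999") {
        eid <- paste(rows$participant_id[j], rows$recall_date[j],
                     rows$entry_index[j], sep = "|")
        if (is.null(assignments[[eid]])) next   # unresolved
        code <- assignments[[eid]]
      }
      frow <- fct[fct$code == code, , drop = FALSE]
      if (nrow(frow) == 0) next                 # unresolved
      prow <- pdb[pdb$food_code_or_group == rows$food_code[j] &
                    pdb$utensil == rows$utensil[j] &
                    pdb$size == rows$utensil_size[j], , drop = FALSE]
      if (nrow(prow) == 0) {
        prow <- pdb[pdb$food_code_or_group == frow$food_group[1] &
                      pdb$utensil == rows$utensil[j] &
                      pdb$size == rows$utensil_size[j], , drop = FALSE]
      }
      grams <- as.numeric(rows$portion_count[j]) *
        as.numeric(prow$grams_per_unit[1])
      ef <- as.numeric(frow$edible_fraction[1])
      for (nm in nuts) {
        out[i, nm] <- out[i, nm] +
          grams * ef * as.numeric(frow[[nm]][1]) / 100
      }
    }
  }
  out
}
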