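`%||%` <- function(x, y) if (is.null(x)) y else x

# Minutes since midnight -> "HH:MM".
format_clock_time <- function(minutes) {
  stopifnot(all(is.na(minutes) | (minutes >= 0 & minutes < 1440)))
  ifelse(is.na(minutes), NA_character_,
         sprintf("%02d:%02d", minutes %/% 60, minutes %% 60))
}

#' Parse 24-hour clock strings
#'
#' Accepts `"HH:MM"` (also `"H:MM"`) and returns minutes since midnight;
#' midnight is 0. Malformed strings are an error naming the offending value.
#'
#' @param x Character vector of clock times.
#' @return Integer vector of minutes in `[0, 1440)`.
#' @export
parse_clock_time <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  keep <- !is.na(x) & nzchar(x)
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x[keep])
  if (any(!ok)) {
    stop("unparseable clock time(s): ",
         paste(unique(x[keep][!ok]), collapse = ", "), call. = FALSE)
  }
  hh <- as.integer(sub(":.*$", "", x[keep]))
  mm <- as.integer(sub("^.*:", "", x[keep]))
  out[keep] <- hh * 60L + mm
  out
}
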