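#' Round half away from zero
#'
#' Printed pharmacovigilance tables round percentages half-up (26.05 -> 26.1),
#' unlike R's banker's rounding. A tiny epsilon absorbs binary representation
#' error on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Strict ISO-8601 date parsing: anything that is not NA/"" or YYYY-MM-DD is a
# parse error, never a silent NA (regulatory exports vary; strictness beats
# misparse).
parse_iso_date <- function(x, field = "date") {
  x <- as.character(x)
  blank <- is.na(x) | x == "" | x == "-"
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- which(!blank & (!ok | is.na(d)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid ISO-8601 %s value(s): %s", field,
                 paste(utils::head(x[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  d
}

# split "a;b;c" seriousness strings into list of criteria vectors
split_seriousness <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

join_seriousness <- function(lst) {
  vapply(lst, function(s) paste(s, collapse = ";"), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
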