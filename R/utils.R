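# Internal helpers shared across modules. All dates in the package are Date
# objects (whole calendar days); every interval written [a, b] is closed on
# both ends.

#' @keywords internal
as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# Round half away from zero ("half-up"), the convention used in printed
# clinical tables; base round() rounds half to even.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Format "count (percent)" with percentages to one decimal, half-up.
#' @keywords internal
fmt_count_pct <- function(count, denom) {
  pct <- ifelse(denom > 0, round_half_up(100 * count / denom, 1), NA_real_)
  ifelse(is.na(pct),
         sprintf("%d (--)", count),
         sprintf("%d (%.1f)", count, pct))
}

# Age in completed years at `on` for someone born on `birth`.
#' @keywords internal
age_on <- function(birth, on) {
  b <- as.POSIXlt(birth)
  o <- as.POSIXlt(on)
  age <- o$year - b$year
  before_bday <- (o$mon < b$mon) | (o$mon == b$mon & o$mday < b$mday)
  age - as.integer(before_bday)
}

# The nth birthday as a Date (Feb 29 birthdays roll to Mar 1 in common years,
# matching how enrollment systems age people up).
#' @keywords internal
nth_birthday <- function(birth, n) {
  b <- as.POSIXlt(birth)
  out <- as.Date(sprintf("%04d-%02d-%02d", b$year + 1900L + n, b$mon + 1L, b$mday),
                 format = "%Y-%m-%d")
  bad <- is.na(out)
  if (any(bad)) {
    out[bad] <- as.Date(sprintf("%04d-03-01", as.POSIXlt(birth[bad])$year + 1900L + n))
  }
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# match_code over codes that may be NA or empty: such cells simply don't match
# (they are caught by row validation, not here).
#' @keywords internal
safe_match <- function(patterns, codes) {
  out <- logical(length(codes))
  ok <- !is.na(codes) & nzchar(codes)
  if (any(ok)) out[ok] <- match_code(patterns, codes[ok])
  out
}
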