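# Small shared helpers: date arithmetic and the paper-style rounding convention.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (so 0.05 -> 0.1),
#' the convention used for all printed percentages in this package. Base R's
#' `round()` rounds half to even, which cannot reproduce tabulated one-decimal
#' percentages such as 3.2 from 140/4309.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to one decimal
#'
#' @param n numerator count(s).
#' @param total denominator.
#' @param digits decimal places (default 1, half away from zero).
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
#' @examples
#' percentage(3273, 4309)  # 76.0
percentage <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round_half_away(100 * n / total, digits)
}

# Shift a Date by whole calendar years; Feb 29 maps to Feb 28 in non-leap years.
add_years <- function(d, n) {
  lt <- as.POSIXlt(d)
  yr <- lt$year + 1900 + n
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  mday <- ifelse(lt$mon == 1 & lt$mday == 29 & !leap, 28, lt$mday)
  as.Date(sprintf("%04d-%02d-%02d", yr, lt$mon + 1, mday))
}

#' Completed years of age at a reference date
#'
#' Standard demographic convention: the number of whole birthdays passed by
#' `reference_date`.
#'
#' @param birth_date Date vector of birth dates.
#' @param reference_date single Date.
#' @return integer vector of ages.
#' @export
completed_years <- function(birth_date, reference_date) {
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(reference_date)
  age <- (r$year - b$year) -
    ((r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday))
  as.integer(age)
}

# Integer day count between two Dates (b - a).
days_between <- function(a, b) as.integer(as.numeric(as.Date(b) - as.Date(a)))

parse_iso_date <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")
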