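## Calendar-month helpers. Months travel through the package as "YYYY-MM"
## strings: they sort lexicographically in chronological order and serialise
## to CSV unchanged.

#' Sequence of calendar months
#'
#' @param from,to months as `"YYYY-MM"` strings (inclusive span).
#' @return character vector of consecutive months.
#' @examples
#' month_seq("2010-11", "2011-02")
#' @export
month_seq <- function(from, to) {
  d_from <- month_first_day(from)
  d_to <- month_first_day(to)
  if (d_from > d_to) stop("`from` must not be after `to`", call. = FALSE)
  format(seq(d_from, d_to, by = "month"), "%Y-%m")
}

#' @rdname month_seq
#' @param month a `"YYYY-MM"` string vector.
#' @return `month_mid_day()`: the 15th of each month as a `Date` — the
#'   evaluation date for event activity; `month_first_day()`: the 1st.
#' @export
month_mid_day <- function(month) {
  as.Date(paste0(check_month(month), "-15"))
}

#' @rdname month_seq
#' @export
month_first_day <- function(month) {
  as.Date(paste0(check_month(month), "-01"))
}

#' @rdname month_seq
#' @return `month_year()`: integer calendar year; `month_of_year()`: integer
#'   1--12.
#' @export
month_year <- function(month) {
  as.integer(substr(check_month(month), 1, 4))
}

#' @rdname month_seq
#' @export
month_of_year <- function(month) {
  as.integer(substr(check_month(month), 6, 7))
}

check_month <- function(month) {
  bad <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", month)
  if (any(bad)) {
    stop("malformed month (expected \"YYYY-MM\"): ",
         paste(unique(month[bad]), collapse = ", "), call. = FALSE)
  }
  month
}
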