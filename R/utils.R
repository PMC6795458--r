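## Shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

nbarti_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "nbarti_error", "error")))
}

#' Round half away from zero
#'
#' Presentation rounding used for all percentages: 0.05 rounds to 0.1,
#' -0.05 to -0.1 (base R's `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_away(88.25, 1)  # 88.3, not 88.2
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## "YYYY-MM" -> list(year, month); strict
parse_year_month <- function(ym) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    nbarti_error(
      sprintf("invalid year-month value(s): %s",
              paste(head(unique(ym[!ok]), 5), collapse = ", ")),
      "nbarti_parse_error")
  }
  list(year = as.integer(substr(ym, 1, 4)),
       month = as.integer(substr(ym, 6, 7)))
}

## month index of a Date relative to a "YYYY-MM" origin (origin -> 0)
month_index_of <- function(dates, origin_ym) {
  o <- parse_year_month(origin_ym)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  (y - o$year) * 12L + (m - o$month)
}

## inverse: month index -> "YYYY-MM" label
month_label_of <- function(idx, origin_ym) {
  o <- parse_year_month(origin_ym)
  tot <- (o$year * 12L + o$month - 1L) + idx
  sprintf("%04d-%02d", tot %/% 12L, tot %% 12L + 1L)
}

## first day of the month `idx` months after origin
month_start_date <- function(idx, origin_ym) {
  as.Date(paste0(month_label_of(idx, origin_ym), "-01"))
}

days_in_month <- function(idx, origin_ym) {
  first <- month_start_date(idx, origin_ym)
  as.integer(month_start_date(idx + 1L, origin_ym) - first)
}

## parse ISO dates strictly, reporting offending row numbers
parse_iso_date <- function(x, what = "date") {
  d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  bad <- c(bad, which(is.na(x) | !nzchar(x)))
  if (length(bad)) {
    nbarti_error(
      sprintf("unparseable %s at row(s) %s",
              what, paste(head(sort(bad), 5), collapse = ", ")),
      "nbarti_parse_error")
  }
  d
}

parse_logical_col <- function(x, what = "flag") {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  if (anyNA(out)) {
    nbarti_error(
      sprintf("malformed %s value(s): %s", what,
              paste(head(unique(x[is.na(out)]), 5), collapse = ", ")),
      "nbarti_parse_error")
  }
  out
}
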