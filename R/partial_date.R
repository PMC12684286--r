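#' Parse partial dates
#'
#' Spontaneous-reporting databases record dates at varying precision: a full
#' day (`"20210517"` / `"2021/05/17"`), a month (`"202105"`), a year
#' (`"2021"`), or nothing. `pd_parse()` decomposes such strings into year /
#' month / day components, leaving absent components `NA`. Strings whose
#' digit content is not 4, 6 or 8 characters long are treated as ambiguous
#' and parse to all-`NA` (downstream analyses exclude them rather than
#' guess).
#'
#' @param x character vector of (partial) date strings. Separators (`/`,
#'   `-`, `.`) are ignored.
#' @return A data.frame with integer columns `year`, `month`, `day` (`NA`
#'   where absent) and `nrow(x)` rows.
#' @examples
#' pd_parse(c("20210517", "2021/05", "2021", "", "garbled"))
#' @export
pd_parse <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  digits <- gsub("[^0-9]", "", x)
  n <- nchar(digits)
  ok <- n %in% c(4L, 6L, 8L)
  year <- ifelse(ok, substr(digits, 1L, 4L), NA)
  month <- ifelse(ok & n >= 6L, substr(digits, 5L, 6L), NA)
  day <- ifelse(ok & n >= 8L, substr(digits, 7L, 8L), NA)
  out <- data.frame(
    year = suppressWarnings(as.integer(year)),
    month = suppressWarnings(as.integer(month)),
    day = suppressWarnings(as.integer(day))
  )
  # out-of-range components invalidate the whole date (ambiguous)
  bad <- (!is.na(out$month) & (out$month < 1L | out$month > 12L)) |
    (!is.na(out$day) & (out$day < 1L | out$day > 31L))
  out[bad, ] <- NA_integer_
  out
}

#' Test whether partial dates are complete calendar dates
#'
#' A partial date is complete iff year, month and day are all present and
#' form a valid calendar date (so `"20210230"` is not complete).
#'
#' @param x character vector of partial-date strings, or a data.frame as
#'   returned by [pd_parse()].
#' @return logical vector.
#' @export
pd_complete <- function(x) {
  pd <- if (is.data.frame(x)) x else pd_parse(x)
  has_all <- !is.na(pd$year) & !is.na(pd$month) & !is.na(pd$day)
  out <- rep(FALSE, nrow(pd))
  if (any(has_all)) {
    iso <- sprintf("%04d-%02d-%02d", pd$year[has_all], pd$month[has_all],
                   pd$day[has_all])
    out[has_all] <- !is.na(as.Date(iso, format = "%Y-%m-%d"))
  }
  out
}

#' Convert complete partial dates to Date
#'
#' @inheritParams pd_complete
#' @return a `Date` vector; `NA` wherever the partial date is incomplete or
#'   invalid.
#' @export
pd_as_date <- function(x) {
  pd <- if (is.data.frame(x)) x else pd_parse(x)
  ok <- pd_complete(pd)
  out <- as.Date(rep(NA_character_, nrow(pd)))
  if (any(ok)) {
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[ok], pd$month[ok],
                               pd$day[ok]))
  }
  out
}

# Render y/m/d integers back to the compact "YYYYMMDD"/"YYYYMM"/"YYYY" form
# (empty string when even the year is missing).
pd_format <- function(year, month = NA, day = NA, sep = "") {
  n <- max(length(year), length(month), length(day))
  year <- rep_len(year, n); month <- rep_len(month, n); day <- rep_len(day, n)
  out <- character(n)
  hy <- !is.na(year)
  out[hy] <- sprintf("%04d", year[hy])
  hm <- hy & !is.na(month)
  out[hm] <- paste0(out[hm], sep, sprintf("%02d", month[hm]))
  hd <- hm & !is.na(day)
  out[hd] <- paste0(out[hd], sep, sprintf("%02d", day[hd]))
  out
}
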