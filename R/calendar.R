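#' Warm-season calendar
#'
#' Builds the day index for a record of consecutive warm seasons. A warm
#' season runs April 1 through September 30 (the Florida Climate Center
#' definition), which is 183 days in every year, leap or not, because
#' February never falls inside it. The day index \code{t} is a bijection
#' between in-season calendar dates and \code{1..T} with
#' \code{T = 183 * n_years}; off-season dates do not exist in the index.
#' Note \code{t} is distinct from the Julian day (day of year).
#'
#' @param start_year first year of the record.
#' @param end_year last year of the record (inclusive).
#' @return An object of class \code{warm_calendar}: a data frame with one row
#'   per in-season day and columns \code{t} (1-based running index),
#'   \code{date} (\code{Date}), \code{year}, \code{year_index} (1-based),
#'   \code{season_day} (1..183 within the season), \code{doy} (Julian day of
#'   year) and \code{month}.
#' @examples
#' cal <- build_calendar(1973, 1973)
#' nrow(cal)  # 183
#' @export
build_calendar <- function(start_year, end_year) {
  if (length(start_year) != 1L || length(end_year) != 1L ||
      !is.finite(start_year) || !is.finite(end_year)) {
    stop("start_year and end_year must be single finite numbers")
  }
  if (start_year > end_year) {
    stop("start_year must not exceed end_year (got ", start_year, " > ",
         end_year, ")")
  }
  years <- seq.int(start_year, end_year)
  dates <- do.call(c, lapply(years, function(y) {
    seq(as.Date(sprintf("%d-04-01", y)), as.Date(sprintf("%d-09-30", y)),
        by = "day")
  }))
  cal <- data.frame(
    t = seq_along(dates),
    date = dates,
    year = as.integer(format(dates, "%Y")),
    stringsAsFactors = FALSE
  )
  cal$year_index <- cal$year - as.integer(start_year) + 1L
  cal$season_day <- cal$t - (cal$year_index - 1L) * 183L
  cal$doy <- as.integer(format(dates, "%j"))
  cal$month <- as.integer(format(dates, "%m"))
  stopifnot(all(cal$season_day >= 1L), all(cal$season_day <= 183L))
  attr(cal, "start_year") <- as.integer(start_year)
  attr(cal, "end_year") <- as.integer(end_year)
  class(cal) <- c("warm_calendar", "data.frame")
  cal
}

#' Number of years covered by a calendar
#' @param calendar a \code{warm_calendar}.
#' @return integer count of warm seasons.
#' @export
n_seasons <- function(calendar) {
  attr(calendar, "end_year") - attr(calendar, "start_year") + 1L
}

#' Map calendar dates to the warm-season day index
#'
#' @param calendar a \code{warm_calendar}.
#' @param dates a \code{Date} vector.
#' @return integer vector of \code{t} indices; \code{NA} for out-of-season
#'   dates.
#' @export
date_to_t <- function(calendar, dates) {
  calendar$t[match(as.Date(dates), calendar$date)]
}

#' Map warm-season day indices back to calendar dates
#' @param calendar a \code{warm_calendar}.
#' @param t integer day indices in \code{1..nrow(calendar)}.
#' @return \code{Date} vector.
#' @export
t_to_date <- function(calendar, t) {
  if (any(t < 1L | t > nrow(calendar), na.rm = TRUE)) {
    stop("t out of range 1..", nrow(calendar))
  }
  calendar$date[t]
}
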