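#' Heat index (NWS procedure)
#'
#' Apparent temperature from air temperature and relative humidity following
#' the procedure the National Weather Service uses operationally: a simple
#' Steadman-average formula is computed first, and whenever it reaches 80 F
#' the full Rothfusz regression is used instead, with the published low-RH
#' and high-RH corrections.
#'
#' The Rothfusz regression is
#' \deqn{HI = -42.379 + 2.04901523 T + 10.14333127 R - 0.22475541 T R
#'   - 6.83783\times10^{-3} T^2 - 5.481717\times10^{-2} R^2
#'   + 1.22874\times10^{-3} T^2 R + 8.5282\times10^{-4} T R^2
#'   - 1.99\times10^{-6} T^2 R^2}
#' with \eqn{T} in degrees Fahrenheit and \eqn{R} in percent. For
#' \eqn{R < 13} and \eqn{80 \le T \le 112} the adjustment
#' \eqn{[(13-R)/4]\sqrt{(17-|T-95|)/17}} is subtracted; for \eqn{R > 85} and
#' \eqn{80 \le T \le 87} the adjustment \eqn{[(R-85)/10][(87-T)/5]} is added.
#'
#' @param temperature_f air temperature, degrees Fahrenheit (vectorised).
#' @param relative_humidity_pct relative humidity, percent, in [0, 100].
#' @return heat index in degrees Fahrenheit.
#' @examples
#' heat_index_f(90, 70)
#' @export
heat_index_f <- function(temperature_f, relative_humidity_pct) {
  t <- as.numeric(temperature_f)
  rh <- as.numeric(relative_humidity_pct)
  if (length(t) != length(rh)) {
    n <- max(length(t), length(rh))
    t <- rep_len(t, n)
    rh <- rep_len(rh, n)
  }
  if (any(!is.finite(t))) stop("temperature must be finite")
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    stop("relative humidity must lie in [0, 100]")
  }
  # Steadman simple formula, already the average with T
  simple <- 0.5 * (t + 61.0 + (t - 68.0) * 1.2 + rh * 0.094)
  hi <- simple
  full <- simple >= 80
  if (any(full)) {
    tf <- t[full]
    rf <- rh[full]
    r <- -42.379 + 2.04901523 * tf + 10.14333127 * rf -
      0.22475541 * tf * rf - 6.83783e-3 * tf^2 - 5.481717e-2 * rf^2 +
      1.22874e-3 * tf^2 * rf + 8.5282e-4 * tf * rf^2 - 1.99e-6 * tf^2 * rf^2
    lo <- rf < 13 & tf >= 80 & tf <= 112
    r[lo] <- r[lo] - ((13 - rf[lo]) / 4) * sqrt((17 - abs(tf[lo] - 95)) / 17)
    hiadj <- rf > 85 & tf >= 80 & tf <= 87
    r[hiadj] <- r[hiadj] + ((rf[hiadj] - 85) / 10) * ((87 - tf[hiadj]) / 5)
    hi[full] <- r
  }
  hi
}

#' Daily maximum heat index from sub-daily records
#'
#' Reduces hourly (or otherwise sub-daily) temperature/humidity records to a
#' per-monitor, per-day maximum heat index grid. Timestamps are taken as
#' local time; the day is the local calendar date. Days with no record are
#' missing. No minimum number of readings per day is imposed.
#'
#' @param hourly data frame with columns \code{monitor_id},
#'   \code{timestamp} (POSIXct or ISO-8601 string), \code{temp_f},
#'   \code{rh_pct}.
#' @param calendar a \code{warm_calendar}.
#' @param network a \code{monitor_network}.
#' @return an \code{hi_grid} of daily maxima.
#' @export
daily_max_heat_index <- function(hourly, calendar, network) {
  values <- matrix(NA_real_, nrow(network), nrow(calendar),
                   dimnames = list(network$monitor_id, NULL))
  if (nrow(hourly)) {
    ts <- hourly$timestamp
    if (!inherits(ts, "POSIXt")) {
      ts <- as.POSIXct(as.character(ts), tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                      "%Y-%m-%d %H:%M"))
    }
    if (anyNA(ts)) stop("unparseable timestamps in hourly records")
    day <- as.Date(format(ts, "%Y-%m-%d"))
    tt <- date_to_t(calendar, day)
    keep <- !is.na(tt) & hourly$monitor_id %in% network$monitor_id
    if (any(keep)) {
      hi <- heat_index_f(hourly$temp_f[keep], hourly$rh_pct[keep])
      row <- match(hourly$monitor_id[keep], network$monitor_id)
      col <- tt[keep]
      agg <- tapply(hi, list(cell = (row - 1L) * nrow(calendar) + col), max)
      cell <- as.integer(names(agg))
      values[cbind((cell - 1L) %/% nrow(calendar) + 1L,
                   (cell - 1L) %% nrow(calendar) + 1L)] <- as.numeric(agg)
    }
  }
  hi_grid(values, calendar, network)
}

#' Read hourly records
#' @param path hourly.csv with columns
#'   \code{monitor_id,timestamp,temp_f,rh_pct}, ISO-8601 timestamps.
#' @return data frame.
#' @export
read_hourly <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(monitor_id = "character"))
}

#' Fahrenheit to Celsius, for report-time conversion
#' @param f degrees Fahrenheit.
#' @param digits decimal places to round to (default 2, report convention).
#' @return degrees Celsius.
#' @export
f_to_c <- function(f, digits = 2) {
  round((f - 32) * 5 / 9, digits)
}
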