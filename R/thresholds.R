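# Warm-season percentile thresholds, per monitor and per region.

#' Per-monitor warm-season percentiles
#'
#' Empirical percentiles of daily maximum heat index over the complete
#' (observed + imputed) record for each monitor, with linear interpolation
#' between closest order statistics.
#'
#' @param completed_grid a complete \code{hi_grid} (no missing cells).
#' @param levels percentile levels in (0, 100); default
#'   \code{c(80, 90, 95, 97.5)}.
#' @return data frame: \code{monitor_id}, \code{region}, one column
#'   \code{p<level>} per level (degrees F).
#' @export
monitor_percentiles <- function(completed_grid,
                                levels = c(80, 90, 95, 97.5)) {
  if (anyNA(completed_grid$values)) {
    stop("grid has missing cells; impute before computing percentiles")
  }
  stopifnot(all(levels > 0), all(levels < 100))
  q <- t(apply(completed_grid$values, 1L, stats::quantile,
               probs = levels / 100, type = 7, names = FALSE))
  if (length(levels) == 1L) q <- matrix(q, ncol = 1L)
  colnames(q) <- paste0("p", sub("\\.?0+$", "", formatC(levels, format = "f",
                                                        digits = 2)))
  out <- data.frame(monitor_id = rownames(completed_grid$values),
                    region = completed_grid$network$region,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(q, row.names = FALSE))
}

#' Daily regional-average series from an incomplete grid
#'
#' For each day, the mean over that day's recorded monitors within the
#' region; \code{NA} when no monitor in the region recorded. This is the
#' ignore-missing-data summary from which regional percentiles are computed.
#'
#' @param observed_grid an \code{hi_grid} (may contain missing cells).
#' @param region a region label of the grid's network.
#' @return numeric vector of length \code{n days}, possibly with \code{NA}.
#' @export
regional_average_series <- function(observed_grid, region) {
  ids <- region_monitors(observed_grid$network, region)
  sub <- observed_grid$values[ids, , drop = FALSE]
  out <- colMeans(sub, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Percentiles of the regional-average series
#'
#' @param observed_grid an \code{hi_grid}.
#' @param levels percentile levels in (0, 100).
#' @return data frame: \code{region}, one \code{p<level>} column per level,
#'   computed over non-missing daily averages.
#' @export
regional_percentiles <- function(observed_grid,
                                 levels = c(80, 90, 95, 97.5)) {
  regs <- network_regions(observed_grid$network)
  rows <- lapply(regs, function(rg) {
    s <- regional_average_series(observed_grid, rg)
    q <- stats::quantile(s, probs = levels / 100, type = 7, names = FALSE,
                         na.rm = TRUE)
    as.data.frame(c(list(region = rg), stats::setNames(
      as.list(q), paste0("p", sub("\\.?0+$", "", formatC(levels, format = "f",
                                                         digits = 2))))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Add Celsius columns to a threshold table
#'
#' Report-time conversion: Celsius values rounded to 2 decimals; internal
#' computation stays in Fahrenheit.
#'
#' @param thresholds a data frame with \code{p...} Fahrenheit columns.
#' @return the data frame with matching \code{..._c} columns appended.
#' @export
thresholds_celsius <- function(thresholds) {
  pcols <- grep("^p", names(thresholds), value = TRUE)
  for (cc in pcols) {
    thresholds[[paste0(cc, "_c")]] <- f_to_c(thresholds[[cc]])
  }
  thresholds
}
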