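# Regional heat-wave identification: the two-condition definition.
#
# A regional heat wave is a maximal run of consecutive in-season days on
# which (1) every monitor in the region exceeds its own 80th warm-season
# percentile on every day, and (2) every monitor exceeds a regional upper
# threshold on at least `min_hot_days` (not necessarily consecutive) days of
# the run. "Exceeds" is strict. Runs never cross a season boundary.

# maximal runs of TRUE within season blocks; ok may contain NA (treated as
# breaking the run)
season_runs <- function(ok, season_year) {
  ok[is.na(ok)] <- FALSE
  n <- length(ok)
  if (!n) return(NULL)
  brk <- c(TRUE, season_year[-1L] != season_year[-n])
  start <- which(ok & (brk | !c(FALSE, ok[-n])))
  if (!length(start)) return(NULL)
  ends <- integer(length(start))
  for (k in seq_along(start)) {
    e <- start[k]
    while (e < n && ok[e + 1L] && season_year[e + 1L] == season_year[e]) {
      e <- e + 1L
    }
    ends[k] <- e
  }
  cbind(start = start, end = ends)
}

#' Find regional heat waves on a completed grid
#'
#' @param region_grid an \code{hi_grid} restricted to (or interpreted as)
#'   one region: every monitor row participates; no missing cells allowed.
#' @param monitor_p80s named numeric vector: each monitor's own 80th
#'   warm-season percentile (degrees F). Names must cover all grid monitors.
#' @param upper_threshold regional upper threshold, degrees F.
#' @param min_hot_days minimum days above the upper threshold per monitor
#'   (and minimum run length); default 3.
#' @param region,method labels copied into the output.
#' @return data frame of heat waves: \code{region}, \code{method},
#'   \code{start}, \code{end} (Dates), \code{days}, \code{upper_threshold};
#'   zero rows when none found.
#' @export
find_heatwaves <- function(region_grid, monitor_p80s, upper_threshold,
                           min_hot_days = 3L, region = NA_character_,
                           method = NA_character_) {
  vals <- region_grid$values
  if (anyNA(vals)) stop("heat-wave search requires a completed grid")
  ids <- rownames(vals)
  if (!all(ids %in% names(monitor_p80s))) {
    stop("missing 80th-percentile thresholds for monitor(s): ",
         paste(setdiff(ids, names(monitor_p80s)), collapse = ", "))
  }
  p80 <- monitor_p80s[ids]
  cond1 <- colSums(vals > p80) == nrow(vals)  # all monitors above own p80
  runs <- season_runs(cond1, region_grid$calendar$year)
  recs <- list()
  if (!is.null(runs)) {
    for (k in seq_len(nrow(runs))) {
      a <- runs[k, 1L]
      b <- runs[k, 2L]
      if (b - a + 1L < min_hot_days) next
      hot_days <- rowSums(vals[, a:b, drop = FALSE] > upper_threshold)
      if (all(hot_days >= min_hot_days)) {
        recs[[length(recs) + 1L]] <- data.frame(
          region = region, method = method,
          start = region_grid$calendar$date[a],
          end = region_grid$calendar$date[b],
          days = b - a + 1L,
          upper_threshold = upper_threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(region = character(), method = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      days = integer(), upper_threshold = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Find heat waves on a regional-average series (ignore-missing mode)
#'
#' Applies the same run logic to the single daily regional-average series:
#' condition (1) is the average exceeding the regional 80th percentile,
#' condition (2) counts days the average exceeds the upper threshold. Days
#' with a missing average break runs.
#'
#' @param average_series numeric daily series (may contain \code{NA}).
#' @param calendar the \code{warm_calendar} aligned with the series.
#' @param regional_p80 80th percentile of the average series, degrees F.
#' @param upper_threshold regional upper threshold, degrees F.
#' @param min_hot_days minimum qualifying days (and minimum run length).
#' @param region,method labels copied into the output.
#' @return data frame with the same columns as \code{\link{find_heatwaves}}.
#' @export
find_heatwaves_ignore_missing <- function(average_series, calendar,
                                          regional_p80, upper_threshold,
                                          min_hot_days = 3L,
                                          region = NA_character_,
                                          method = "ignore") {
  stopifnot(length(average_series) == nrow(calendar))
  cond1 <- average_series > regional_p80
  runs <- season_runs(cond1, calendar$year)
  recs <- list()
  if (!is.null(runs)) {
    for (k in seq_len(nrow(runs))) {
      a <- runs[k, 1L]
      b <- runs[k, 2L]
      if (b - a + 1L < min_hot_days) next
      nhot <- sum(average_series[a:b] > upper_threshold, na.rm = TRUE)
      if (nhot >= min_hot_days) {
        recs[[length(recs) + 1L]] <- data.frame(
          region = region, method = method,
          start = calendar$date[a], end = calendar$date[b],
          days = b - a + 1L, upper_threshold = upper_threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(region = character(), method = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      days = integer(), upper_threshold = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Regional benchmark threshold
#'
#' The highest candidate upper threshold still yielding at least one heat
#' wave in the evaluation window. The heat-wave count is non-increasing in
#' the threshold, so a descending linear scan finds the benchmark.
#'
#' @param finder a function \code{function(upper) -> heat-wave data frame}
#'   already restricted to the evaluation years.
#' @param candidate_thresholds numeric candidates (degrees F); default the
#'   integer grid 95..120.
#' @return list with \code{benchmark} (degrees F, or \code{NA} if even the
#'   smallest candidate yields none) and \code{found} (logical).
#' @export
regional_benchmark <- function(finder, candidate_thresholds = 95:120) {
  stopifnot(length(candidate_thresholds) > 0)
  cand <- sort(candidate_thresholds, decreasing = TRUE)
  for (u in cand) {
    if (nrow(finder(u)) >= 1L) {
      return(list(benchmark = u, found = TRUE))
    }
  }
  list(benchmark = NA_real_, found = FALSE)
}

#' Restrict a grid to a region and/or year window
#'
#' @param grid an \code{hi_grid}.
#' @param region a region label, or \code{NULL} to keep all monitors.
#' @param years integer years to keep, or \code{NULL} to keep all.
#' @return the restricted \code{hi_grid}.
#' @export
subset_grid <- function(grid, region = NULL, years = NULL) {
  vals <- grid$values
  net <- grid$network
  cal <- grid$calendar
  if (!is.null(region)) {
    ids <- region_monitors(net, region)
    keep <- net$monitor_id %in% ids
    net2 <- net[keep, , drop = FALSE]
    attr(net2, "distance_km") <- network_distances(net)[keep, keep,
                                                        drop = FALSE]
    class(net2) <- class(net)
    net <- net2
    vals <- vals[keep, , drop = FALSE]
  }
  if (!is.null(years)) {
    kc <- cal$year %in% years
    cal2 <- cal[kc, , drop = FALSE]
    cal2$t <- seq_len(nrow(cal2))
    cal2$year_index <- cal2$year - min(cal2$year) + 1L
    for (a in c("start_year", "end_year")) {
      attr(cal2, a) <- as.integer(if (a == "start_year") min(cal2$year)
                                  else max(cal2$year))
    }
    class(cal2) <- class(cal)
    cal <- cal2
    vals <- vals[, kc, drop = FALSE]
  }
  hi_grid(vals, cal, net)
}
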