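# Synthetic heat-index study generator: a Florida-like monitor network with
# seasonal cycle, slow year trend, day-to-day anomaly persistence, distance-
# decaying spatial correlation, and month/monitor-structured missingness.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic heat-index study
#'
#' Defaults emulate the scale of a 43-monitor Florida network observed over
#' the 1973-2012 warm seasons: a seasonal cycle peaking in mid-July, a small
#' warming trend, persistent day-to-day anomalies that are spatially
#' correlated with an exponential decay at synoptic scale, monitor-specific
#' level offsets, and missingness that is heavier in April/May/September than
#' in June-August and varies strongly by monitor (most monitors record nearly
#' completely; a few are sparse recorders).
#'
#' @param n_monitors number of monitors.
#' @param start_year,end_year warm-season record span.
#' @param bounding_box named numeric vector \code{lat_min,lat_max,lon_min,
#'   lon_max} in decimal degrees.
#' @param n_regions number of contiguous latitude-band regions.
#' @param seasonal_mean mean daily maximum heat index, degrees F.
#' @param seasonal_amplitude amplitude (degrees F) of the annual cosine cycle
#'   peaking at day-of-year 196 (mid-July).
#' @param year_trend trend in degrees F per decade.
#' @param ar_coefficient day-to-day anomaly persistence phi, |phi| < 1.
#' @param spatial_range exponential correlation range of the anomaly field, km.
#' @param spatial_sill marginal variance of the anomaly field, F^2
#'   (innovations are scaled by 1 - phi^2 so this is the stationary variance).
#' @param nugget white measurement-noise variance, F^2.
#' @param monitor_offsets_sd sd (degrees F) of monitor-specific level offsets.
#' @param missing_rate_warm_months missingness probability in June-August.
#' @param missing_rate_cool_months missingness probability in April, May,
#'   September.
#' @param monitor_missing_multipliers per-monitor factors multiplying the
#'   month rate (capped at 0.95). \code{NULL} draws them from the seed:
#'   log-normal around 1 with roughly 7 percent of monitors made sparse
#'   recorders (multiplier 8).
#' @param seed integer seed; all three generator operations are
#'   deterministic given it.
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_monitors = 43,
                             start_year = 1973,
                             end_year = 2012,
                             bounding_box = c(lat_min = 24.5, lat_max = 31.0,
                                              lon_min = -87.6, lon_max = -80.0),
                             n_regions = 6,
                             seasonal_mean = 84,
                             seasonal_amplitude = 12,
                             year_trend = 0.3,
                             ar_coefficient = 0.6,
                             spatial_range = 300,
                             spatial_sill = 16,
                             nugget = 1,
                             monitor_offsets_sd = 1.5,
                             missing_rate_warm_months = 0.05,
                             missing_rate_cool_months = 0.18,
                             monitor_missing_multipliers = NULL,
                             seed = 42) {
  stopifnot(n_monitors >= 1, start_year <= end_year,
            abs(ar_coefficient) < 1, spatial_range > 0,
            spatial_sill >= 0, nugget >= 0,
            missing_rate_warm_months >= 0, missing_rate_warm_months < 1,
            missing_rate_cool_months >= 0, missing_rate_cool_months < 1)
  if (is.null(monitor_missing_multipliers)) {
    monitor_missing_multipliers <- with_seed(seed + 104729L, {
      m <- exp(stats::rnorm(n_monitors, 0, 0.5))
      n_sparse <- max(0L, round(0.07 * n_monitors))
      if (n_sparse > 0L) {
        m[sample.int(n_monitors, n_sparse)] <- 8
      }
      m
    })
  }
  stopifnot(length(monitor_missing_multipliers) == n_monitors,
            all(monitor_missing_multipliers >= 0))
  structure(list(
    n_monitors = as.integer(n_monitors),
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    bounding_box = bounding_box,
    n_regions = as.integer(n_regions),
    seasonal_mean = seasonal_mean,
    seasonal_amplitude = seasonal_amplitude,
    year_trend = year_trend,
    ar_coefficient = ar_coefficient,
    spatial_range = spatial_range,
    spatial_sill = spatial_sill,
    nugget = nugget,
    monitor_offsets_sd = monitor_offsets_sd,
    missing_rate_warm_months = missing_rate_warm_months,
    missing_rate_cool_months = missing_rate_cool_months,
    monitor_missing_multipliers = monitor_missing_multipliers,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Read a synthetic configuration from YAML
#' @param path YAML file whose keys are \code{synthetic_config} arguments.
#' @return a \code{synthetic_config}.
#' @export
read_synthetic_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$bounding_box)) {
    args$bounding_box <- unlist(args$bounding_box)
  }
  do.call(synthetic_config, args)
}

#' Generate a monitor network
#'
#' Monitors are placed uniformly at random in the bounding box and assigned
#' to contiguous latitude-band regions (south to north, labels
#' \code{R1..Rk}) of near-equal size.
#'
#' @param config a \code{synthetic_config}.
#' @return a \code{monitor_network}.
#' @export
generate_network <- function(config) {
  bb <- config$bounding_box
  if (!(bb["lat_max"] > bb["lat_min"]) || !(bb["lon_max"] > bb["lon_min"])) {
    stop("degenerate bounding box")
  }
  n <- config$n_monitors
  with_seed(config$seed + 1L, {
    lat <- stats::runif(n, bb["lat_min"], bb["lat_max"])
    lon <- stats::runif(n, bb["lon_min"], bb["lon_max"])
    k <- min(config$n_regions, n)
    band <- if (k == 1L) rep("R1", n) else {
      as.character(cut(rank(lat, ties.method = "first"),
                       breaks = k, labels = paste0("R", seq_len(k))))
    }
    monitor_network(sprintf("M%03d", seq_len(n)), lat, lon, band)
  })
}

# Annual cosine peaking at day-of-year 196 (mid-July).
season_cycle <- function(doy, amplitude) {
  amplitude * cos(2 * pi * (doy - 196) / 365.25)
}

#' Generate a fully observed ground-truth grid
#'
#' \code{value(i, t) = seasonal_mean + cycle(doy_t) + trend (year_t - start)/10
#' + offset_i + a(i, t) + nugget noise}, where the anomaly field follows
#' \code{a(., t) = phi a(., t - 1) + eta_t}, the innovations \code{eta_t}
#' being jointly Gaussian across monitors with covariance
#' \code{(1 - phi^2) sill exp(-d / range)} so the stationary marginal variance
#' is exactly \code{sill}. The chain restarts at its stationary distribution
#' at the start of each warm season.
#'
#' @param config a \code{synthetic_config}.
#' @param network a \code{monitor_network} (defaults to
#'   \code{generate_network(config)}).
#' @param calendar a \code{warm_calendar} (defaults to the config span).
#' @return a fully observed \code{hi_grid}.
#' @export
generate_truth <- function(config,
                           network = generate_network(config),
                           calendar = build_calendar(config$start_year,
                                                     config$end_year)) {
  n <- nrow(network)
  T <- nrow(calendar)
  d <- network_distances(network)
  with_seed(config$seed + 2L, {
    offsets <- if (config$monitor_offsets_sd > 0) {
      stats::rnorm(n, 0, config$monitor_offsets_sd)
    } else rep(0, n)
    vals <- matrix(0, n, T, dimnames = list(network$monitor_id, NULL))
    # deterministic surface
    surf <- config$seasonal_mean +
      season_cycle(calendar$doy, config$seasonal_amplitude) +
      config$year_trend * (calendar$year - config$start_year) / 10
    vals <- vals + matrix(surf, n, T, byrow = TRUE) + offsets
    # spatially correlated AR(1) anomalies, restarted each season
    if (config$spatial_sill > 0) {
      phi <- config$ar_coefficient
      sig_marg <- config$spatial_sill * exp(-d / config$spatial_range)
      L_marg <- t(chol(sig_marg + diag(1e-10, n)))
      L_innov <- L_marg * sqrt(1 - phi^2)
      a <- numeric(n)
      for (t in seq_len(T)) {
        if (calendar$season_day[t] == 1L) {
          a <- as.numeric(L_marg %*% stats::rnorm(n))
        } else {
          a <- phi * a + as.numeric(L_innov %*% stats::rnorm(n))
        }
        vals[, t] <- vals[, t] + a
      }
    }
    if (config$nugget > 0) {
      vals <- vals + matrix(stats::rnorm(n * T, 0, sqrt(config$nugget)), n, T)
    }
    hi_grid(vals, calendar, network)
  })
}

#' Mask cells of a fully observed grid
#'
#' Each cell is masked independently with probability
#' \code{month_rate x monitor_multiplier}, capped at 0.95 (missing completely
#' at random within month-by-monitor strata). The true values of masked
#' cells are returned alongside so downstream imputation can be scored.
#'
#' @param truth a fully observed \code{hi_grid}.
#' @param config a \code{synthetic_config}.
#' @return list with \code{observed} (the masked \code{hi_grid}) and
#'   \code{heldout} (data frame \code{monitor_id,date,true_hi_f} of masked
#'   cells).
#' @export
apply_missingness <- function(truth, config) {
  if (anyNA(truth$values)) stop("truth grid must be fully observed")
  n <- nrow(truth$values)
  T <- ncol(truth$values)
  warm <- truth$calendar$month %in% 6:8
  month_rate <- ifelse(warm, config$missing_rate_warm_months,
                       config$missing_rate_cool_months)
  p <- outer(config$monitor_missing_multipliers, month_rate)
  p <- pmin(p, 0.95)
  with_seed(config$seed + 3L, {
    drop <- matrix(stats::runif(n * T), n, T) < p
    vals <- truth$values
    vals[drop] <- NA_real_
    idx <- which(drop, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    heldout <- data.frame(
      monitor_id = rownames(truth$values)[idx[, 1L]],
      date = truth$calendar$date[idx[, 2L]],
      true_hi_f = truth$values[idx],
      stringsAsFactors = FALSE
    )
    list(observed = hi_grid(vals, truth$calendar, truth$network),
         heldout = heldout)
  })
}
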