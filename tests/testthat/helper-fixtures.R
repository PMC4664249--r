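# Shared fixtures and independent brute-force oracles.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_monitors = 8, start_year = 2006, end_year = 2009,
                   n_regions = 2, seed = 101)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

tiny_grid <- function(...) {
  cfg <- tiny_config(...)
  net <- generate_network(cfg)
  truth <- generate_truth(cfg, net)
  list(cfg = cfg, net = net, truth = truth,
       masked = apply_missingness(truth, cfg))
}

# hand-built 2-monitor grid over one short "calendar" for finder toys; the
# real calendar is used but only the first n days carry values of interest
toy_region_grid <- function(values, start_year = 2008) {
  n_days <- ncol(values)
  cal <- build_calendar(start_year, start_year)
  full <- matrix(80, nrow(values), nrow(cal))
  full[, seq_len(n_days)] <- values
  rownames(full) <- sprintf("T%02d", seq_len(nrow(values)))
  net <- monitor_network(rownames(full),
                         latitude = 27 + seq_len(nrow(values)) * 0.3,
                         longitude = -81 + seq_len(nrow(values)) * 0.3,
                         region = rep("TOY", nrow(values)))
  hi_grid(full, cal, net)
}

# Brute-force heat-wave enumeration: all O(T^2) periods, keep qualifying
# periods not contained in a longer qualifying one.
bf_heatwaves <- function(vals, p80, upper, min_hot_days = 3L,
                         season_year = rep(1L, ncol(vals))) {
  n_days <- ncol(vals)
  qual <- list()
  for (a in seq_len(n_days)) {
    for (b in a:n_days) {
      if (b - a + 1L < min_hot_days) next
      if (length(unique(season_year[a:b])) > 1L) next
      sub <- vals[, a:b, drop = FALSE]
      c1 <- all(sub > p80)
      c2 <- all(rowSums(sub > upper) >= min_hot_days)
      if (c1 && c2) qual[[length(qual) + 1L]] <- c(a, b)
    }
  }
  if (!length(qual)) return(matrix(integer(), 0, 2))
  q <- do.call(rbind, qual)
  keep <- vapply(seq_len(nrow(q)), function(i) {
    !any(q[, 1L] <= q[i, 1L] & q[, 2L] >= q[i, 2L] &
           (q[, 2L] - q[, 1L] > q[i, 2L] - q[i, 1L]))
  }, TRUE)
  q[keep, , drop = FALSE]
}

# Brute-force ignore-missing variant on a single series.
bf_heatwaves_series <- function(s, p80, upper, min_hot_days = 3L) {
  n_days <- length(s)
  qual <- list()
  for (a in seq_len(n_days)) {
    for (b in a:n_days) {
      if (b - a + 1L < min_hot_days) next
      sub <- s[a:b]
      if (anyNA(sub)) next
      if (all(sub > p80) && sum(sub > upper) >= min_hot_days) {
        qual[[length(qual) + 1L]] <- c(a, b)
      }
    }
  }
  if (!length(qual)) return(matrix(integer(), 0, 2))
  q <- do.call(rbind, qual)
  keep <- vapply(seq_len(nrow(q)), function(i) {
    !any(q[, 1L] <= q[i, 1L] & q[, 2L] >= q[i, 2L] &
           (q[, 2L] - q[, 1L] > q[i, 2L] - q[i, 1L]))
  }, TRUE)
  q[keep, , drop = FALSE]
}

# Hand-rolled order-statistic percentile with linear interpolation.
bf_percentile <- function(x, level) {
  x <- sort(x)
  h <- (length(x) - 1) * level / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
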