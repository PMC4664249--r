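# simulate directly from the lag model: y_t = b0 + b1 y_{t-1} + e_t with
# exponential spatial errors within each day
simulate_lag_model <- function(net, cal, b0, b1, sill, rng, seed) {
  set.seed(seed)
  d <- network_distances(net)
  n <- nrow(net)
  L <- t(chol(sill * exp(-d / rng) + diag(1e-10, n)))
  vals <- matrix(NA_real_, n, nrow(cal),
                 dimnames = list(net$monitor_id, NULL))
  mu_st <- b0 / (1 - b1)
  for (t in seq_len(nrow(cal))) {
    e <- as.numeric(L %*% rnorm(n))
    vals[, t] <- if (cal$season_day[t] == 1L) mu_st + e else
      b0 + b1 * vals[, t - 1L] + e
  }
  vals
}

test_that("lag-model parameters are recovered from simulated data", {
  set.seed(44)
  n <- 43
  net <- monitor_network(sprintf("M%02d", 1:n), runif(n, 24.5, 31),
                         runif(n, -87.6, -80), rep("R1", n))
  cal <- build_calendar(2003, 2012)  # 10 seasons
  b0 <- 36; b1 <- 0.6; sill <- 9; rng <- 300
  vals <- simulate_lag_model(net, cal, b0, b1, sill, rng, seed = 45)
  g <- hi_grid(vals, cal, net)
  fit <- fit_spatiotemporal(g)
  expect_lt(abs(fit$beta0 - b0), 2 * fit$se[1])
  expect_lt(abs(fit$beta1 - b1), 2 * fit$se[2])
  expect_lt(abs(fit$range - rng) / rng, 0.25)
  expect_lt(abs(fit$sill - sill) / sill, 0.25)
})

test_that("a zero lag coefficient is not invented", {
  set.seed(46)
  n <- 20
  net <- monitor_network(sprintf("M%02d", 1:n), runif(n, 24.5, 31),
                         runif(n, -87.6, -80), rep("R1", n))
  cal <- build_calendar(2008, 2012)
  vals <- simulate_lag_model(net, cal, b0 = 90, b1 = 0, sill = 9,
                             rng = 250, seed = 47)
  fit <- fit_spatiotemporal(hi_grid(vals, cal, net))
  expect_lt(abs(fit$beta1), 2 * fit$se[2])
})

test_that("perfect persistence drives beta1 to one and the sill to zero", {
  net <- monitor_network(c("A", "B", "C"), c(26, 27.5, 29),
                         c(-81, -82.5, -84), rep("R1", 3))
  cal <- build_calendar(2011, 2012)
  start_vals <- c(88, 95, 102)
  vals <- matrix(start_vals, 3, nrow(cal),
                 dimnames = list(c("A", "B", "C"), NULL))
  fit <- fit_spatiotemporal(hi_grid(vals, cal, net))
  expect_equal(fit$beta1, 1, tolerance = 1e-3)
  expect_lt(fit$sill, 1e-4)
})

test_that("spatio-temporal imputation preserves observed cells exactly", {
  fx <- tiny_grid(n_monitors = 6, start_year = 2009, end_year = 2011,
                  n_regions = 1)
  g <- fx$masked$observed
  done <- impute_spatiotemporal(g)
  expect_false(anyNA(done$values))
  obs <- !is.na(g$values)
  expect_identical(done$values[obs], g$values[obs])
  expect_identical(impute_spatiotemporal(fx$truth)$values, fx$truth$values)
})

test_that("no usable lag pairs is an error", {
  net <- monitor_network("A", 27, -81, "R1")
  cal <- build_calendar(2012, 2012)
  vals <- matrix(NA_real_, 1, 183, dimnames = list("A", NULL))
  vals[1, seq(1, 183, by = 2)] <- 90  # alternating: never two adjacent days
  expect_error(fit_spatiotemporal(hi_grid(vals, cal, net)),
               "no usable lag pairs")
})
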