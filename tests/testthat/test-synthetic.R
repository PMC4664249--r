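test_that("generators are deterministic given the seed", {
  cfg <- tiny_config()
  expect_identical(generate_network(cfg), generate_network(cfg))
  net <- generate_network(cfg)
  expect_identical(generate_truth(cfg, net)$values,
                   generate_truth(cfg, net)$values)
  tr <- generate_truth(cfg, net)
  a1 <- apply_missingness(tr, cfg)
  a2 <- apply_missingness(tr, cfg)
  expect_identical(a1$observed$values, a2$observed$values)
  expect_identical(a1$heldout, a2$heldout)
})

test_that("generated networks have valid geometry and regions", {
  cfg <- tiny_config(n_monitors = 43, n_regions = 6)
  net <- generate_network(cfg)
  d <- network_distances(net)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  # haversine oracle via geosphere on a few pairs
  for (k in 1:5) {
    i <- k; j <- k + 10
    expect_equal(d[i, j],
                 geosphere::distHaversine(
                   c(net$longitude[i], net$latitude[i]),
                   c(net$longitude[j], net$latitude[j]), r = 6371000) / 1000)
  }
  expect_length(network_regions(net), 6L)
  expect_true(all(table(net$region) >= 1))
  one <- generate_network(tiny_config(n_monitors = 1))
  expect_equal(nrow(one), 1L)
})

test_that("zeroing all stochastic terms leaves the closed-form surface", {
  cfg <- tiny_config(n_monitors = 3, seasonal_amplitude = 0, year_trend = 0,
                     spatial_sill = 0, nugget = 0, monitor_offsets_sd = 0)
  tr <- generate_truth(cfg, generate_network(cfg))
  expect_true(all(tr$values == cfg$seasonal_mean))
})

test_that("anomalies lose day-to-day memory when phi is zero", {
  cfg <- synthetic_config(n_monitors = 2, start_year = 1973, end_year = 2012,
                          seasonal_amplitude = 0, year_trend = 0,
                          monitor_offsets_sd = 0, nugget = 0,
                          ar_coefficient = 0, seed = 5)
  tr <- generate_truth(cfg, generate_network(cfg))
  x <- tr$values[1, ] - cfg$seasonal_mean
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(length(x)))
})

test_that("pairwise correlations decay like the exponential model", {
  cfg <- synthetic_config(n_monitors = 43, start_year = 1973,
                          end_year = 2012, seasonal_amplitude = 0,
                          year_trend = 0, monitor_offsets_sd = 0, nugget = 0,
                          seed = 9)
  net <- generate_network(cfg)
  tr <- generate_truth(cfg, net)
  x <- tr$values - cfg$seasonal_mean
  cc <- cor(t(x))
  d <- network_distances(net)
  up <- upper.tri(d)
  # empirical-variogram oracle: log-linear fit of correlation on distance
  fit <- lm(log(pmax(cc[up], 1e-4)) ~ d[up])
  range_hat <- -1 / coef(fit)[2]
  expect_lt(abs(range_hat - cfg$spatial_range) / cfg$spatial_range, 0.25)
})

test_that("missingness hits its month-level targets", {
  cfg <- synthetic_config(n_monitors = 20, start_year = 1993,
                          end_year = 2012,
                          missing_rate_warm_months = 0.05,
                          missing_rate_cool_months = 0.20,
                          monitor_missing_multipliers = rep(1, 20), seed = 3)
  fx <- apply_missingness(generate_truth(cfg, generate_network(cfg)), cfg)
  miss <- is.na(fx$observed$values)
  warm <- fx$observed$calendar$month %in% 6:8
  for (w in c(TRUE, FALSE)) {
    p <- if (w) 0.05 else 0.20
    n <- sum(warm == w) * 20
    obs_rate <- mean(miss[, warm == w])
    expect_lt(abs(obs_rate - p), 3 * sqrt(p * (1 - p) / n))
  }
  # warm rate zero keeps June-August fully observed
  cfg0 <- tiny_config(missing_rate_warm_months = 0,
                      monitor_missing_multipliers = rep(1, 8))
  fx0 <- apply_missingness(generate_truth(cfg0, generate_network(cfg0)),
                           cfg0)
  expect_false(anyNA(fx0$observed$values[, fx0$observed$calendar$month
                                         %in% 6:8]))
  # zero rates reproduce the truth
  cfgz <- tiny_config(missing_rate_warm_months = 0,
                      missing_rate_cool_months = 0,
                      monitor_missing_multipliers = rep(1, 8))
  trz <- generate_truth(cfgz, generate_network(cfgz))
  fxz <- apply_missingness(trz, cfgz)
  expect_identical(fxz$observed$values, trz$values)
  expect_equal(nrow(fxz$heldout), 0L)
})
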