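test_that("two equidistant monitors average symmetrically", {
  fit <- list(sill = 9, range = 200, nugget = 0)
  obs <- data.frame(longitude = c(-81.5, -80.5), latitude = c(27, 27),
                    value = c(90, 100))
  tgt <- data.frame(longitude = -81, latitude = 27)
  p <- krige_day(fit, obs, tgt)
  expect_equal(as.numeric(p), 95.0, tolerance = 1e-9)
  expect_equal(rowSums(attr(p, "weights")), 1, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kriging weights match a dense linear-system oracle", {
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    lon <- runif(n, -87, -80)
    lat <- runif(n, 25, 31)
    sill <- runif(1, 2, 30)
    rng <- runif(1, 50, 600)
    fit <- list(sill = sill, range = rng, nugget = 0)
    obs <- data.frame(longitude = lon, latitude = lat,
                      value = runif(n, 80, 105))
    tlon <- runif(1, -87, -80)
    tlat <- runif(1, 25, 31)
    p <- krige_day(fit, obs, data.frame(longitude = tlon, latitude = tlat))
    # oracle: assemble and solve the ordinary-kriging system directly
    pts <- cbind(c(lon, tlon), c(lat, tlat))
    D <- matrix(0, n + 1, n + 1)
    for (i in seq_len(n + 1)) for (j in seq_len(n + 1)) {
      D[i, j] <- geosphere::distHaversine(pts[i, ], pts[j, ],
                                          r = 6371000) / 1000
    }
    K <- rbind(cbind(sill * exp(-D[1:n, 1:n] / rng), 1), c(rep(1, n), 0))
    rhs <- c(sill * exp(-D[1:n, n + 1] / rng), 1)
    w_oracle <- solve(K, rhs)[1:n]
    expect_equal(as.numeric(attr(p, "weights")), w_oracle,
                 tolerance = 1e-8)
    expect_equal(as.numeric(p), sum(w_oracle * obs$value),
                 tolerance = 1e-8)
    expect_equal(sum(attr(p, "weights")), 1, tolerance = 1e-8)
  }
})

test_that("kriging axioms: exactness, constants, degenerate fields", {
  fit <- list(sill = 16, range = 300, nugget = 0)
  set.seed(8)
  obs <- data.frame(longitude = runif(6, -85, -81),
                    latitude = runif(6, 26, 30), value = runif(6, 85, 102))
  # zero nugget: prediction at an observed site equals the observation
  p <- krige_day(fit, obs, obs[3, c("longitude", "latitude")])
  expect_equal(as.numeric(p), obs$value[3], tolerance = 1e-6)
  # constant field reproduced exactly everywhere
  obs$value <- 97
  p <- krige_day(fit, obs, data.frame(longitude = -83.3, latitude = 27.7))
  expect_equal(as.numeric(p), 97, tolerance = 1e-8)
  # zero-sill (all values equal) fit predicts the constant
  p0 <- krige_day(list(sill = 0, range = 100, nugget = 0), obs,
                  data.frame(longitude = -84, latitude = 28))
  expect_equal(as.numeric(p0), 97)
})

test_that("degenerate day inputs signal their fallbacks", {
  fx <- tiny_grid(n_monitors = 4, start_year = 2011, end_year = 2011)
  g <- fx$truth
  g$values[2:4, 5] <- NA  # one observed monitor on day 5
  expect_error(fit_spatial_day(g, 5), class = "hotspell_fallback_required")
  # duplicated coordinates are named
  fit <- list(sill = 4, range = 100, nugget = 0)
  obs <- data.frame(longitude = c(-81, -81, -82), latitude = c(27, 27, 28),
                    value = c(90, 91, 92))
  expect_error(krige_day(fit, obs, data.frame(longitude = -80,
                                              latitude = 27)),
               "duplicated observation coordinates")
  # constant day: sill collapses to zero
  g2 <- fx$truth
  g2$values[, 7] <- 95
  f <- fit_spatial_day(g2, 7)
  expect_equal(f$sill, 0)
})

test_that("REML recovers the exponential range over replicate days", {
  set.seed(12)
  n <- 43
  lon <- runif(n, -87.6, -80)
  lat <- runif(n, 24.5, 31)
  net <- monitor_network(sprintf("M%02d", 1:n), lat, lon, rep("R1", n))
  d <- network_distances(net)
  sill <- 16
  rng <- 300
  L <- t(chol(sill * exp(-d / rng) + diag(1e-10, n)))
  est <- matrix(NA_real_, 500, 2)
  for (k in 1:500) {
    y <- 90 + as.numeric(L %*% rnorm(n))
    f <- hotspell:::fit_exp_reml(y, d)
    est[k, ] <- c(f$sill, f$range)
  }
  expect_lt(abs(median(est[, 2]) - rng) / rng, 0.25)
  expect_lt(abs(median(est[, 1]) - sill) / sill, 0.35)
})

test_that("spatial imputation fills every gap and honors fallbacks", {
  fx <- tiny_grid(n_monitors = 6, start_year = 2010, end_year = 2011,
                  n_regions = 1)
  g <- fx$masked$observed
  # blank out an entire day to force the monthly-mean fallback
  g$values[, 40] <- NA
  done <- impute_spatial(g)
  expect_false(anyNA(done$values))
  obs <- !is.na(g$values)
  expect_identical(done$values[obs], g$values[obs])
  dg <- attr(done, "diagnostics")
  expect_gte(dg$n_fallback_days, 1L)
  # the blanked day used each monitor's own all-years monthly mean
  mm <- hotspell:::monthly_mean_table(g)
  expect_equal(done$values[, 40],
               mm[, as.character(g$calendar$month[40])],
               ignore_attr = TRUE)
  # identity on a fully observed grid
  expect_identical(impute_spatial(fx$truth)$values, fx$truth$values)
})
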