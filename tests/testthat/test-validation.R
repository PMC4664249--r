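test_that("hold-out allocation rounds per-day counts half to even", {
  cal <- build_calendar(2012, 2012)
  n <- 43
  net <- monitor_network(sprintf("M%02d", 1:n), runif(n, 25, 31),
                         runif(n, -87, -80), rep("R1", n))
  g <- hi_grid(matrix(90, n, 183, dimnames = list(net$monitor_id, NULL)),
               cal, net)
  ho <- draw_holdout(g, 0.10, seed = 2)
  per_day <- table(ho$cells$col)
  expect_true(all(per_day == 4))  # round(4.3) = 4
  expect_equal(nrow(ho$cells), 4 * 183)
  # determinism
  ho2 <- draw_holdout(g, 0.10, seed = 2)
  expect_identical(ho$cells, ho2$cells)
  expect_false(identical(ho$cells, draw_holdout(g, 0.10, seed = 3)$cells))
})

test_that("held-out cells come only from observed cells and partition them", {
  fx <- tiny_grid(n_monitors = 6, start_year = 2009, end_year = 2010)
  g <- fx$masked$observed
  ho <- draw_holdout(g, 0.15, seed = 7)
  idx <- cbind(ho$cells$row, ho$cells$col)
  expect_true(all(!is.na(g$values[idx])))
  reduced <- mask_holdout(g, ho)
  expect_true(all(is.na(reduced$values[idx])))
  # union of held-out and remaining observed equals original observed
  expect_equal(sum(!is.na(reduced$values)) + nrow(ho$cells),
               sum(!is.na(g$values)))
  # every cell outside the hold-out is untouched
  restored <- reduced$values
  restored[idx] <- g$values[idx]
  expect_identical(restored, g$values)
})

test_that("rmspe follows its definition and subset rules", {
  expect_equal(rmspe(c(1, 3), c(2, 5)), sqrt(2.5))
  expect_equal(rmspe(1:10, 1:10), 0)
  expect_error(rmspe(1:3, 1:4), "equal length")
  expect_warning(r <- rmspe(c(1, 2), c(90, 91), subset_threshold_f = 100),
                 "no qualifying pairs")
  expect_true(is.na(r))
  # subset on the true value only
  expect_equal(rmspe(c(0, 95), c(99, 101), subset_threshold_f = 100), 6)
  # invariance to ordering
  set.seed(1)
  p <- rnorm(50); tr <- rnorm(50)
  o <- sample(50)
  expect_equal(rmspe(p, tr), rmspe(p[o], tr[o]))
})

test_that("an oracle imputer scores exactly zero for any fraction and seed", {
  fx <- tiny_grid(n_monitors = 16, start_year = 2010, end_year = 2011)
  g <- fx$masked$observed
  oracle <- function(grid) fx$truth
  for (fr in c(0.1, 0.2)) {
    rep <- compare_methods(g, methods = list(oracle = oracle),
                           fraction = fr, seed = 13)
    expect_equal(rep$overall$rmspe_f, 0)
    expect_true(all(rep$per_monitor$rmspe_f == 0))
  }
})

test_that("compare_methods scores all methods on one shared draw", {
  fx <- tiny_grid(n_monitors = 6, start_year = 2008, end_year = 2010,
                  n_regions = 1)
  g <- fx$masked$observed
  shift1 <- function(grid) {
    done <- fx$truth
    done$values <- done$values + 1
    done$values[!is.na(grid$values)] <- grid$values[!is.na(grid$values)]
    hi_grid(done$values, grid$calendar, grid$network)
  }
  rep <- compare_methods(g, methods = list(oracle = function(grid) fx$truth,
                                           biased = shift1),
                         fraction = 0.1, seed = 21)
  expect_equal(rep$overall$rmspe_f[rep$overall$method == "oracle"], 0)
  expect_equal(rep$overall$rmspe_f[rep$overall$method == "biased"], 1)
  expect_true(all(rep$winners$best == "oracle"))
  expect_true(all(rep$winners$worst == "biased"))
})
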