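test_that("percentiles follow the order-statistic interpolation convention", {
  cal <- build_calendar(2012, 2012)
  net <- monitor_network("A", 27, -81, "R1")
  mk <- function(x) hi_grid(matrix(x, 1, 183, dimnames = list("A", NULL)),
                            cal, net)
  g <- mk(rep(c(1, 2, 3), 61))
  expect_equal(monitor_percentiles(g, 50)$p50, 2)
  g <- mk(rep(96.5, 183))
  tab <- monitor_percentiles(g)
  expect_true(all(tab[, c("p80", "p90", "p95", "p97.5")] == 96.5))
  # 1..100 padded grid against the hand-rolled oracle
  x <- c(1:100, rep(50.5, 83))
  g <- mk(x)
  for (lv in c(80, 90, 95, 97.5)) {
    expect_equal(monitor_percentiles(g, lv)[[2 + 1]],
                 bf_percentile(x, lv))
  }
  # monotone across levels, and missing cells are refused
  expect_true(all(diff(unlist(tab[1, c("p80", "p90", "p95", "p97.5")]))
                  >= 0))
  gm <- mk(c(NA, rep(90, 182)))
  expect_error(monitor_percentiles(gm), "impute")
})

test_that("regional averages use only recorded monitors", {
  cal <- build_calendar(2012, 2012)
  net <- monitor_network(c("A", "B", "C"), c(26, 27, 28), c(-81, -82, -83),
                         c("RG", "RG", "OTHER"))
  vals <- matrix(NA_real_, 3, 183, dimnames = list(c("A", "B", "C"), NULL))
  vals[, 1] <- c(100, 104, 999)
  vals["A", 2] <- 98
  vals["C", 3] <- 999  # other region only
  g <- hi_grid(vals, cal, net)
  s <- regional_average_series(g, "RG")
  expect_equal(s[1], 102)
  expect_equal(s[2], 98)
  expect_true(is.na(s[3]))
  # brute-force per-day enumeration over a mixed 5-day pattern
  vals[, 4] <- c(90, NA, 1)
  vals[, 5] <- c(NA, 91, 1)
  g <- hi_grid(vals, cal, net)
  s <- regional_average_series(g, "RG")
  manual <- sapply(1:5, function(t) {
    v <- vals[c("A", "B"), t]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  expect_equal(s[1:5], manual)
})

test_that("the finder matches brute-force enumeration on toy grids", {
  # constructed 10-day toy: condition 1 holds on days 3-8, each monitor has
  # exactly 3 days above the upper threshold inside that window
  v <- rbind(c(80, 80, 91, 95, 96, 91, 95, 91, 80, 80),
             c(80, 80, 92, 96, 92, 96, 96, 92, 80, 80))
  p80 <- c(T01 = 90, T02 = 91)
  upper <- 94
  g <- toy_region_grid(v)
  hw <- find_heatwaves(g, p80, upper)
  expect_equal(nrow(hw), 1L)
  expect_equal(hw$start, g$calendar$date[3])
  expect_equal(hw$end, g$calendar$date[8])
  bf <- bf_heatwaves(v, p80, upper)
  expect_equal(unname(bf), matrix(c(3L, 8L), 1))
  # randomized toys against the oracle
  set.seed(99)
  for (rep in 1:25) {
    nm <- sample(2:3, 1)
    nd <- sample(10:20, 1)
    vv <- matrix(sample(c(88, 92, 95, 99), nm * nd, replace = TRUE), nm, nd)
    p <- setNames(rep(90, nm), sprintf("T%02d", seq_len(nm)))
    up <- 94
    gg <- toy_region_grid(vv)
    got <- find_heatwaves(gg, p, up)
    want <- bf_heatwaves(vv, p, up)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(date_to_t(gg$calendar, got$start), unname(want[, 1]))
      expect_equal(date_to_t(gg$calendar, got$end), unname(want[, 2]))
    }
    # monitor-order invariance
    perm <- sample(nm)
    gperm <- toy_region_grid(vv[perm, , drop = FALSE])
    rownames(gperm$values) <- sprintf("T%02d", seq_len(nm))
    got2 <- find_heatwaves(gperm, setNames(p[perm],
                                           sprintf("T%02d", seq_len(nm))),
                           up)
    expect_equal(got2$start, got$start)
    # periods are disjoint and maximal by construction of the oracle
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
  }
})

test_that("condition 2 discards runs without enough hot days", {
  v <- rbind(c(91, 95, 95, 91, 91, 91, 80),
             c(92, 96, 92, 96, 96, 92, 80))
  p80 <- c(T01 = 90, T02 = 91)
  hw <- find_heatwaves(toy_region_grid(v), p80, upper_threshold = 94)
  expect_equal(nrow(hw), 0L)  # monitor 1 exceeds upper on only 2 days
  # all-cold grid yields nothing
  hw0 <- find_heatwaves(toy_region_grid(matrix(70, 2, 10)), p80, 94)
  expect_equal(nrow(hw0), 0L)
  # unknown monitors in the threshold table are an error
  expect_error(find_heatwaves(toy_region_grid(v), c(X = 90), 94),
               "threshold")
})

test_that("ignore-missing runs break on missing averages", {
  cal <- build_calendar(2010, 2010)
  s <- rep(NA_real_, 183)
  s[1:12] <- c(95, 96, 97, 95, 96, NA, 97, 95, 96, 97, 80, 80)
  hw <- find_heatwaves_ignore_missing(s, cal, regional_p80 = 90,
                                      upper_threshold = 94)
  expect_equal(nrow(hw), 2L)  # the NA splits one stretch into two runs
  expect_equal(date_to_t(cal, hw$start), c(1L, 7L))
  expect_equal(date_to_t(cal, hw$end), c(5L, 10L))
  bf <- bf_heatwaves_series(s[1:12], 90, 94)
  expect_equal(unname(bf), cbind(c(1L, 7L), c(5L, 10L)))
  # series entirely above both thresholds: one full-season period
  s2 <- rep(100, 183)
  hw2 <- find_heatwaves_ignore_missing(s2, cal, 90, 94)
  expect_equal(nrow(hw2), 1L)
  expect_equal(hw2$days, 183L)
})

test_that("benchmark search equals exhaustive scan and is monotone", {
  v <- rbind(c(80, 80, 103, 105, 106, 104, 105, 104, 80, 80),
             c(80, 80, 104, 106, 104, 105, 106, 105, 80, 80))
  p80 <- c(T01 = 90, T02 = 91)
  g <- toy_region_grid(v)
  finder <- function(u) find_heatwaves(g, p80, u)
  bm <- regional_benchmark(finder, 95:120)
  # exhaustive search oracle; the count is non-increasing in the threshold
  counts <- sapply(95:120, function(u) nrow(finder(u)))
  expect_equal(bm$benchmark, max((95:120)[counts >= 1]))
  expect_equal(bm$benchmark, 104)
  expect_true(all(diff(counts) <= 0))
  # all-cold toy: no benchmark
  g0 <- toy_region_grid(matrix(70, 2, 10))
  bm0 <- regional_benchmark(function(u) find_heatwaves(g0, p80, u), 95:120)
  expect_false(bm0$found)
  expect_true(is.na(bm0$benchmark))
})
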