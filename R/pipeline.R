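# End-to-end synthetic study: generate -> mask -> (validate) -> impute by
# each method -> thresholds -> regional benchmarks -> heat waves, with all
# tables written as CSV and a machine-readable run manifest.

#' Run the full synthetic heat-wave study
#'
#' Deterministic given \code{config$seed} (stage sub-seeds are derived by
#' fixed offsets). The four missing-data approaches are run side by side:
#' ignoring missing data (regional-average series) and imputing by the
#' temporal, spatial and spatio-temporal models. For each region and
#' approach, the regional benchmark (highest upper threshold yielding at
#' least one heat wave in the evaluation window) is searched on an integer
#' Fahrenheit candidate grid and the corresponding heat waves recorded.
#'
#' @param config a \code{synthetic_config}.
#' @param out_dir directory for output tables, or \code{NULL} to skip
#'   writing.
#' @param methods imputation methods to run.
#' @param eval_years evaluation window for benchmarks and heat waves
#'   (default the last 8 years of the record).
#' @param candidate_thresholds benchmark candidate grid, degrees F.
#' @param holdout_fraction fraction for the method-comparison hold-out;
#'   set to \code{NULL} to skip the validation stage.
#' @param levels percentile levels.
#' @param verbose log stage progress and fallback counts to stderr.
#' @return a list bundle: \code{network}, \code{observed}, \code{heldout},
#'   \code{validation} (an \code{rmspe_report} or \code{NULL}),
#'   \code{completed} (list per method), \code{thresholds} (per method),
#'   \code{regional} (ignore-missing percentiles), \code{benchmarks},
#'   \code{heatwaves}, \code{fallbacks} (counts), \code{manifest}.
#' @export
run_full_study <- function(config,
                           out_dir = NULL,
                           methods = c("temporal", "spatial",
                                       "spatiotemporal"),
                           eval_years = NULL,
                           candidate_thresholds = 95:120,
                           holdout_fraction = 0.10,
                           levels = c(80, 90, 95, 97.5),
                           verbose = FALSE) {
  log_msg <- function(...) if (verbose) message("run_full_study: ", ...)
  calendar <- build_calendar(config$start_year, config$end_year)
  if (is.null(eval_years)) {
    eval_years <- seq.int(max(config$start_year, config$end_year - 7L),
                          config$end_year)
  }
  log_msg("generating network and truth")
  network <- generate_network(config)
  truth <- generate_truth(config, network, calendar)
  masked <- apply_missingness(truth, config)
  observed <- masked$observed

  validation <- NULL
  if (!is.null(holdout_fraction)) {
    log_msg("hold-out validation at fraction ", holdout_fraction)
    validation <- compare_methods(observed, methods,
                                  fraction = holdout_fraction,
                                  seed = config$seed + 11L)
  }

  completed <- list()
  thresholds <- list()
  fallbacks <- list()
  for (m in methods) {
    log_msg("imputing with ", m, " model")
    completed[[m]] <- builtin_imputers()[[m]](observed)
    d <- attr(completed[[m]], "diagnostics")
    fallbacks[[m]] <- switch(
      m,
      temporal = list(year_effect_dropped = sum(d$year_effect_dropped)),
      spatial = list(fallback_days = d$n_fallback_days,
                     pooled_days = d$n_pooled_days),
      spatiotemporal = list(first_day_fallbacks = d$n_first_day_fallbacks),
      list())
    thresholds[[m]] <- monitor_percentiles(completed[[m]], levels)
  }
  regional <- regional_percentiles(observed, levels)

  log_msg("searching benchmarks and heat waves")
  regions <- network_regions(network)
  bench_rows <- list()
  hw_rows <- list()
  for (rg in regions) {
    # imputed approaches: per-monitor thresholds, all monitors must qualify
    for (m in methods) {
      thr <- thresholds[[m]]
      thr <- thr[thr$region == rg, ]
      p80 <- stats::setNames(thr$p80, thr$monitor_id)
      gsub_eval <- subset_grid(completed[[m]], region = rg,
                               years = eval_years)
      finder <- function(u) {
        find_heatwaves(gsub_eval, p80, u, region = rg, method = m)
      }
      bm <- regional_benchmark(finder, candidate_thresholds)
      bench_rows[[length(bench_rows) + 1L]] <- data.frame(
        region = rg, method = m, benchmark_f = bm$benchmark,
        stringsAsFactors = FALSE)
      if (bm$found) {
        hw_rows[[length(hw_rows) + 1L]] <- finder(bm$benchmark)
      }
    }
    # ignore-missing approach: regional-average series
    avg <- regional_average_series(observed, rg)
    p80r <- regional$p80[regional$region == rg]
    keep <- calendar$year %in% eval_years
    cal_eval <- calendar[keep, , drop = FALSE]
    class(cal_eval) <- class(calendar)
    avg_eval <- avg[keep]
    finder_ig <- function(u) {
      find_heatwaves_ignore_missing(avg_eval, cal_eval, p80r, u,
                                    region = rg)
    }
    bm <- regional_benchmark(finder_ig, candidate_thresholds)
    bench_rows[[length(bench_rows) + 1L]] <- data.frame(
      region = rg, method = "ignore", benchmark_f = bm$benchmark,
      stringsAsFactors = FALSE)
    if (bm$found) {
      hw_rows[[length(hw_rows) + 1L]] <- finder_ig(bm$benchmark)
    }
  }
  benchmarks <- do.call(rbind, bench_rows)
  heatwaves <- if (length(hw_rows)) `rownames<-`(do.call(rbind, hw_rows), NULL) else
    data.frame(region = character(), method = character(),
               start = as.Date(character()), end = as.Date(character()),
               days = integer(), upper_threshold = numeric())
  for (m in names(fallbacks)) {
    log_msg(m, " fallbacks: ",
            paste(names(fallbacks[[m]]), unlist(fallbacks[[m]]),
                  sep = "=", collapse = ", "))
  }

  bundle <- list(config = config, network = network, observed = observed,
                 heldout = masked$heldout, validation = validation,
                 completed = completed, thresholds = thresholds,
                 regional = regional, benchmarks = benchmarks,
                 heatwaves = heatwaves, fallbacks = fallbacks,
                 eval_years = eval_years)
  if (!is.null(out_dir)) {
    write_study_bundle(bundle, out_dir)
  }
  bundle
}

num4 <- function(x) sprintf("%.4f", x)

#' Write a study bundle to CSV tables
#'
#' Emits \code{monitors.csv}, \code{daily.csv} (observed grid),
#' \code{heldout.csv}, per-method \code{completed_<method>.csv} and
#' \code{thresholds_<method>.csv} (degrees F plus Celsius rounded to 2
#' decimals), \code{thresholds_regional.csv}, \code{benchmarks.csv},
#' \code{heatwaves.csv}, \code{rmspe.csv} when validation ran, and
#' \code{manifest.json}.
#'
#' @param bundle output of \code{\link{run_full_study}}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_study_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_network(bundle$network, fp("monitors.csv"))
  write_grid(bundle$observed, fp("daily.csv"))
  write_heldout(bundle$heldout, fp("heldout.csv"))
  for (m in names(bundle$completed)) {
    write_grid(bundle$completed[[m]], fp(paste0("completed_", m, ".csv")))
    thr <- thresholds_celsius(bundle$thresholds[[m]])
    pf <- grep("^p.*[^c]$", names(thr), value = TRUE)
    thr[pf] <- lapply(thr[pf], num4)
    utils::write.csv(thr, fp(paste0("thresholds_", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  reg <- thresholds_celsius(bundle$regional)
  pf <- grep("^p.*[^c]$", names(reg), value = TRUE)
  reg[pf] <- lapply(reg[pf], num4)
  utils::write.csv(reg, fp("thresholds_regional.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(bundle$benchmarks, fp("benchmarks.csv"),
                   row.names = FALSE, quote = FALSE)
  hw <- bundle$heatwaves
  hw$start <- format(hw$start, "%Y-%m-%d")
  hw$end <- format(hw$end, "%Y-%m-%d")
  utils::write.csv(hw, fp("heatwaves.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$validation)) {
    ov <- bundle$validation$overall
    ov[-1L] <- lapply(ov[-1L], num4)
    utils::write.csv(ov, fp("rmspe.csv"), row.names = FALSE, quote = FALSE)
    pm <- bundle$validation$per_monitor
    pm$rmspe_f <- num4(pm$rmspe_f)
    utils::write.csv(pm, fp("rmspe_per_monitor.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(
    seed = bundle$config$seed,
    n_monitors = bundle$config$n_monitors,
    years = c(bundle$config$start_year, bundle$config$end_year),
    eval_years = range(bundle$eval_years),
    methods = names(bundle$completed),
    fallbacks = bundle$fallbacks,
    n_heatwaves = nrow(bundle$heatwaves))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
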