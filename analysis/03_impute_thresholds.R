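#!/usr/bin/env Rscript
# Stage 3: impute the observed grid by each method and estimate warm-season
# percentile thresholds.
#
# Produces, per method, the completed grid (completed_<method>.csv) and the
# per-monitor 80/90/95/97.5th percentiles in F and C
# (thresholds_<method>.csv), plus the ignore-missing regional-average
# percentiles (thresholds_regional.csv).

source("analysis/00_config.R")

observed <- read_grid(file.path(data_dir, "daily.csv"),
                      file.path(data_dir, "monitors.csv"),
                      study_years[1], study_years[2])

imputers <- list(temporal = impute_temporal,
                 spatial = impute_spatial,
                 spatiotemporal = function(g) impute_spatiotemporal(g))
for (m in names(imputers)) {
  message("imputing with the ", m, " model ...")
  done <- imputers[[m]](observed)
  write_grid(done, file.path(data_dir, paste0("completed_", m, ".csv")))
  thr <- thresholds_celsius(monitor_percentiles(done))
  write.csv(thr, file.path(results_dir, paste0("thresholds_", m, ".csv")),
            row.names = FALSE)
  message(sprintf("  %s: p80 spans %.1f-%.1f F, p97.5 spans %.1f-%.1f F",
                  m, min(thr$p80), max(thr$p80), min(thr$p97.5),
                  max(thr$p97.5)))
}

reg <- thresholds_celsius(regional_percentiles(observed))
write.csv(reg, file.path(results_dir, "thresholds_regional.csv"),
          row.names = FALSE)
message("regional-average (ignore-missing) percentiles written")
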