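#!/usr/bin/env Rscript
# Stage 2: hold-out comparison of the imputation methods.
#
# Draws a 10% day-stratified hold-out from the observed grid, refits the
# temporal, spatial and spatio-temporal models without those cells, and
# scores predictions at the held-out cells: RMSPE overall, RMSPE for true
# values above 100 F, per-monitor RMSPE and per-monitor best/worst flags.
# Writes rmspe.csv and rmspe_per_monitor.csv under results/.

source("analysis/00_config.R")

observed <- read_grid(file.path(data_dir, "daily.csv"),
                      file.path(data_dir, "monitors.csv"),
                      study_years[1], study_years[2])
report <- compare_methods(observed, fraction = 0.10,
                          seed = study_seed + 11L)

print(report)
ov <- report$overall
write.csv(ov, file.path(results_dir, "rmspe.csv"), row.names = FALSE)
write.csv(report$per_monitor, file.path(results_dir, "rmspe_per_monitor.csv"),
          row.names = FALSE)
write.csv(report$winners, file.path(results_dir, "rmspe_winners.csv"),
          row.names = FALSE)

best <- ov$method[which.min(ov$rmspe_f)]
message(sprintf(
  "lowest RMSPE overall and on >100F truth: %s (%.2f F overall); temporal shrinks extremes (mean signed error %.2f F)",
  best, min(ov$rmspe_f),
  ov$mean_signed_error_extreme_f[ov$method == "temporal"]))
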