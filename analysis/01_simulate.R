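#!/usr/bin/env Rscript
# Stage 1: simulate the study data.
#
# Generates the 43-monitor Florida-like network, the fully observed
# ground-truth daily-maximum heat-index grid over the 1973-2012 warm
# seasons, and the observed grid after month/monitor-structured missingness.
# Writes monitors.csv, daily.csv (observed records) and heldout.csv (the
# true values of masked cells, for later scoring) under results/data/.

source("analysis/00_config.R")

network <- generate_network(study_config)
truth <- generate_truth(study_config, network)
masked <- apply_missingness(truth, study_config)

write_network(network, file.path(data_dir, "monitors.csv"))
write_grid(masked$observed, file.path(data_dir, "daily.csv"))
write_heldout(masked$heldout, file.path(data_dir, "heldout.csv"))

obs_frac <- mean(!is.na(masked$observed$values))
warm <- masked$observed$calendar$month %in% 6:8
message(sprintf(
  "simulated %d monitors x %d days (%d cells); %.1f%% observed overall, %.1f%% missing in JJA vs %.1f%% in AMS",
  nrow(network), ncol(truth$values), grid_cell_count(truth),
  100 * obs_frac,
  100 * mean(is.na(masked$observed$values[, warm])),
  100 * mean(is.na(masked$observed$values[, !warm]))))
message("wrote ", data_dir, "/{monitors,daily,heldout}.csv")
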