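# Shared settings for the analysis drivers. Each numbered script can be run
# from the repository root after installing the package:
#   Rscript analysis/01_simulate.R
suppressMessages(library(hotspell))

study_seed <- 42L
results_dir <- "results"
data_dir <- file.path(results_dir, "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

study_config <- synthetic_config(seed = study_seed)
study_years <- c(study_config$start_year, study_config$end_year)
eval_years <- 2005:2012
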