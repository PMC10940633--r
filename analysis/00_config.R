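# Shared configuration for the analysis scripts.
#
# The scripts run the workflow at a demonstration profile: the full
# methodology (5 spatial folds x 2 algorithms, 250-km blocks, quartile
# retention) with fewer CV repeats and shallower forests than the
# production defaults so the whole sequence completes in a few minutes on
# a laptop. Raise n_repeats to 30 and rf_trees to 500 for a full run.

library(refugiaSDM)

RESULTS <- file.path("results")
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

analysis_config <- pipeline_config(
  n_repeats = 6,
  rf_trees = 200,
  n_permutations = 5,
  seed = 20260901
)

cache_file <- function(name) file.path(CACHE, paste0(name, ".rds"))
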