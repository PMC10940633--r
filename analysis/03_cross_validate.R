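# Stage 3 — repeated spatial-block cross-validation.
#
# Fits the binomial GAM (k = 4) and the probability forest on every
# train split of the repeated five-fold spatial CV (250-km blocks) and
# evaluates each on its held-out fold: AUC, TSS, sensitivity,
# specificity, TSS-optimal threshold, binary maps for both scenarios,
# permutation importances and response curves.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config
st1 <- readRDS(cache_file("01_simulate"))
dataset <- readRDS(cache_file("02_dataset"))

runs <- run_cross_validation(
  dataset,
  list(present = st1$sea$present, future = st1$sea$future),
  n_folds = cfg$n_folds, n_repeats = cfg$n_repeats,
  algorithms = cfg$algorithms, seed = cfg$seed,
  block_size_km = cfg$block_size_km, k_max = cfg$k_max,
  rf_trees = cfg$rf_trees, n_permutations = cfg$n_permutations,
  response_curves = cfg$response_curves,
  curve_points = cfg$curve_points,
  curve_background_max = cfg$curve_background_max)

met <- runs_metrics(runs)
write.csv(met, file.path(RESULTS, "run_metrics.csv"), row.names = FALSE)
saveRDS(runs, cache_file("03_runs"))

ok <- met[met$status == "ok", ]
cat(sprintf("%d model runs (%d successful).\n", nrow(met), nrow(ok)))
for (alg in unique(ok$algorithm))
  cat(sprintf(
    "  %s: AUC %.3f +/- %.3f, TSS %.2f +/- %.2f, sens %.2f, spec %.2f\n",
    toupper(alg),
    mean(ok$auc[ok$algorithm == alg]), sd(ok$auc[ok$algorithm == alg]),
    mean(ok$tss[ok$algorithm == alg]), sd(ok$tss[ok$algorithm == alg]),
    mean(ok$sensitivity[ok$algorithm == alg]),
    mean(ok$specificity[ok$algorithm == alg])))
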