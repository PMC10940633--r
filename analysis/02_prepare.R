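# Stage 2 — model-ready dataset.
#
# Implants pseudo-absences in the presence-only zones at the survey's
# presence/absence ratio (never below 1000 m), aggregates to one record
# per working-grid cell with presence priority, extracts the predictor
# values, and screens predictor collinearity (advisory only).

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config
st1 <- readRDS(cache_file("01_simulate"))

occ <- add_pseudo_absences(st1$occ, cfg$presence_only_regions,
                           st1$sea$present$layers$bathymetry,
                           seed = cfg$seed)
agg <- aggregate_to_grid(occ, cfg$grid, seed = cfg$seed)
dataset <- extract_predictors(agg, st1$sea$present)
coll <- collinearity_report(dataset)

write.csv(occ, file.path(RESULTS, "occurrences_prepared.csv"),
          row.names = FALSE)
write.csv(dataset, file.path(RESULTS, "dataset_aggregated.csv"),
          row.names = FALSE)
write.csv(coll, file.path(RESULTS, "collinearity.csv"), row.names = FALSE)
saveRDS(dataset, cache_file("02_dataset"))

cat(sprintf(
  "Added %d pseudo-absences; aggregated %d records to %d cells (%d presences).\n",
  sum(occ$source == "pseudo_absence"), nrow(occ), nrow(dataset),
  sum(dataset$detected == 1)))
if (any(coll$flagged))
  cat("Flagged predictor pairs (|rho| > 0.7):\n",
      paste(sprintf("  %s ~ %s (rho = %.2f)",
                    coll$var1[coll$flagged], coll$var2[coll$flagged],
                    coll$rho[coll$flagged]), collapse = "\n"), "\n")
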