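# Stage 4 — model retention and ensemble suitability.
#
# Discards the first AUC quartile of runs, averages the remaining binary
# maps into the ensemble habitat suitability index for both scenarios,
# and calibrates the ensemble threshold on the aggregated dataset. Also
# summarises the ensemble-mean response curves and importances.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config
dataset <- readRDS(cache_file("02_dataset"))
runs <- readRDS(cache_file("03_runs"))

retained <- retain_models(runs)
suit_p <- ensemble_suitability(retained, "present")
suit_f <- ensemble_suitability(retained, "future")
thr <- ensemble_threshold(suit_p, dataset)

write_raster(suit_p, file.path(RESULTS, "suitability_present.asc"))
write_raster(suit_f, file.path(RESULTS, "suitability_future.asc"))
saveRDS(list(retained = retained, suit_p = suit_p, suit_f = suit_f,
             thr = thr), cache_file("04_ensemble"))

# ensemble-mean depth response of the GAMs and mean importances
gam_runs <- Filter(function(r) r$algorithm == "gam", retained)
depth_curve <- mean_response_curve(lapply(gam_runs,
                                          function(r) r$curves$bathymetry))
write.csv(depth_curve, file.path(RESULTS, "gam_depth_response.csv"),
          row.names = FALSE)
imp <- do.call(rbind, lapply(retained, function(r)
  cbind(r$importance, algorithm = r$algorithm)))
imp_mean <- aggregate(auc_loss ~ predictor + algorithm, imp, mean)
write.csv(imp_mean, file.path(RESULTS, "importance_mean.csv"),
          row.names = FALSE)

cat(sprintf(
  "Retained %d of %d runs; ensemble threshold %.3f.\nGAM depth response peaks at %.0f m.\nMean importances (AUC loss):\n",
  length(retained), length(runs), thr,
  -depth_curve$x[which.max(depth_curve$y)]))
print(imp_mean[order(imp_mean$algorithm, -imp_mean$auc_loss), ],
      row.names = FALSE)
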