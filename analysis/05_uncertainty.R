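# Stage 5 — uncertainty surfaces.
#
# Three complementary views: (1) calibration uncertainty, the mean/sd
# ratio of the retained binary maps; (2) algorithm disagreement between
# the GAM-only and RF-only sub-ensembles; (3) model-observation
# comparison against ordinary kriging of the survey detections within a
# 20-km buffer.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config
st1 <- readRDS(cache_file("01_simulate"))
dataset <- readRDS(cache_file("02_dataset"))
ens <- readRDS(cache_file("04_ensemble"))

calib <- calibration_uncertainty(ens$retained, "present")
disagree <- algorithm_disagreement(ens$retained, dataset)

survey <- st1$occ[st1$occ$source == "survey", ]
kriged <- krige_occurrence(survey, cfg$grid, buffer_km = cfg$buffer_km,
                           seed = cfg$seed)
bin_p <- binarize_ensemble(ens$suit_p, ens$thr)
agree <- observation_agreement(bin_p, kriged, cfg$occ_threshold)

write_raster(calib, file.path(RESULTS, "calibration_uncertainty.asc"))
write_raster(disagree, file.path(RESULTS, "algorithm_disagreement.asc"))
write_raster(kriged, file.path(RESULTS, "kriged_occurrence.asc"))
write_raster(agree, file.path(RESULTS, "observation_agreement.asc"))
saveRDS(list(kriged = kriged, bin_p = bin_p), cache_file("05_uncertainty"))

cls <- attr(agree, "classes")
n <- table(factor(agree$values, levels = cls, labels = names(cls)))
cat(sprintf(
  "Calibration ratio: median %.2f (%d unanimous cells set nodata).\nAlgorithm disagreement: %.1f%% of valid cells.\nModel-observation agreement within the surveyed footprint: %.1f%%.\n",
  median(calib$values, na.rm = TRUE), attr(calib, "n_sd_zero"),
  100 * mean(disagree$values %in% c(3, 4), na.rm = TRUE),
  100 * (n[["agreement_suitable"]] + n[["agreement_unsuitable"]]) /
    sum(n[c("agreement_suitable", "disagreement_suitable",
            "agreement_unsuitable", "disagreement_unsuitable")])))
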