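# Stage 6 — climate projection and refugia classification.
#
# Binarises the present and future ensemble suitability at the ensemble
# threshold, restricts to the study area (< 2000 m), and classifies each
# cell as habitat gain, loss, climate refugium, or absence, with area
# accounting.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config
st1 <- readRDS(cache_file("01_simulate"))
ens <- readRDS(cache_file("04_ensemble"))

bat <- st1$sea$present$layers$bathymetry
bin_p <- mask_study_area(binarize_ensemble(ens$suit_p, ens$thr), bat,
                         cfg$max_depth_m)
bin_f <- mask_study_area(binarize_ensemble(ens$suit_f, ens$thr), bat,
                         cfg$max_depth_m)
change <- classify_change(bin_p, bin_f)
s <- habitat_change_summary(change)

write_raster(change$map, file.path(RESULTS, "habitat_change.asc"))
jsonlite::write_json(s, file.path(RESULTS, "habitat_change_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
saveRDS(list(change = change, bin_p = bin_p), cache_file("06_projection"))

cat(sprintf(
  "Of the %.0f km2 suitable today, %.1f%% is lost by the future scenario\nand %.1f%% persists as climate refugia; gains add %.1f%%.\n",
  s$areas_km2[["loss"]] + s$areas_km2[["refugia"]],
  s$loss_pct, s$refugia_pct, s$gain_pct))
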