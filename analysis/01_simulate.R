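# Stage 1 — synthetic seascape and occurrence survey.
#
# Generates the study system: five environmental predictor layers for the
# present and a warmed (RCP 8.5-like) future, the known truth suitability
# surface, a patchy trawling-effort field, three regional seas, and an
# occurrence dataset mixing survey presence/absence stations with two
# presence-only zones.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config

sea <- generate_seascape(cfg$grid, cfg$truth, seed = cfg$seed)
occ <- sample_occurrences(
  sea$truth, sea$present$layers$bathymetry,
  survey_design(cfg$n_survey_stations, cfg$presence_only_regions,
                cfg$n_presence_only, seed = cfg$seed))

for (nm in names(sea$present$layers))
  write_raster(sea$present$layers[[nm]],
               file.path(RESULTS, paste0(nm, ".asc")))
write_raster(sea$future$layers$temperature,
             file.path(RESULTS, "temperature_rcp85.asc"))
write_raster(sea$fishing, file.path(RESULTS, "fishing_effort.asc"))
write.csv(occ, file.path(RESULTS, "occurrences_raw.csv"),
          row.names = FALSE)
saveRDS(list(sea = sea, occ = occ), cache_file("01_simulate"))

d <- -sea$present$layers$bathymetry$values
cat(sprintf(
  "Seascape %dx%d cells: depth 5-%.0f m, %d survey stations (%.1f%% presences),\n%d presence-only records in %d zones.\n",
  cfg$grid$n_rows, cfg$grid$n_cols, max(d),
  sum(occ$source == "survey"),
  100 * mean(occ$detected[occ$source == "survey"]),
  sum(occ$source == "presence_only"),
  length(cfg$presence_only_regions)))
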