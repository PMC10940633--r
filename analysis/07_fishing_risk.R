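# Stage 7 — fishing-risk overlay.
#
# Discretises trawling effort into quartile risk classes and overlays
# them on three habitat footprints — observed presence (kriged), present
# suitable habitat, and climate refugia — summarised as km2 per regional
# sea and risk level.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config
st1 <- readRDS(cache_file("01_simulate"))
un <- readRDS(cache_file("05_uncertainty"))
pj <- readRDS(cache_file("06_projection"))

risk <- risk_levels(st1$sea$fishing)
observed <- binarize_ensemble(un$kriged, cfg$occ_threshold)
cls <- attr(pj$change$map, "classes")
refugia <- pj$change$map
refugia$values <- ifelse(is.na(refugia$values), NA_real_,
                         as.numeric(refugia$values == cls[["refugia"]]))

overlays <- list(observed = overlay_risk(risk, observed, st1$sea$regions),
                 suitable = overlay_risk(risk, pj$bin_p, st1$sea$regions),
                 refugia = overlay_risk(risk, refugia, st1$sea$regions))

write_raster(risk$map, file.path(RESULTS, "fishing_risk.asc"))
for (nm in names(overlays))
  write.csv(overlays[[nm]],
            file.path(RESULTS, paste0("overlay_", nm, ".csv")),
            row.names = FALSE)

cat(sprintf("Risk quartile edges: %.2f / %.2f / %.2f h km-2 yr-1.\n",
            risk$edges[1], risk$edges[2], risk$edges[3]))
for (nm in names(overlays)) {
  tab <- overlays[[nm]]
  hi <- tab$risk_class %in% c("high", "very_high") & tab$region == "all"
  cat(sprintf(
    "  %s footprint: %.0f km2 total, %.0f km2 (%.0f%%) under high or very high effort.\n",
    nm, sum(tab$area_km2[tab$region == "all"]), sum(tab$area_km2[hi]),
    100 * sum(tab$area_km2[hi]) /
      max(sum(tab$area_km2[tab$region == "all"]), 1)))
}
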