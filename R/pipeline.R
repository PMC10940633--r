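#' Pipeline configuration
#'
#' Collects every tunable of the workflow with the standard working
#' defaults: 0.25-degree synthetic working grid, 250-km spatial blocks,
#' 5 folds x 30 repeats x 2 algorithms, GAM basis cap k = 4, 500-tree
#' forests, first-quartile AUC retention, 20-km kriging buffer, 0.5
#' observed-occurrence threshold. The `profile` arguments (`n_repeats`,
#' `rf_trees`, `n_permutations`, `response_curves`) are the knobs scaled
#' down for quick runs; everything else is the methodology itself.
#'
#' @param grid working [grid_spec()].
#' @param truth a [truth_params()].
#' @param n_survey_stations,n_presence_only survey design sizes.
#' @param presence_only_regions boxes, or NULL for
#'   [default_presence_only_regions()].
#' @param block_size_km,n_folds,n_repeats,algorithms CV settings.
#' @param k_max,rf_trees,n_permutations,response_curves,curve_points,curve_background_max
#'   learner and per-run output settings.
#' @param buffer_km kriging prediction buffer (km).
#' @param occ_threshold kriged-occurrence binarisation threshold.
#' @param krige_max_points survey records are subsampled to this many
#'   before kriging to bound the dense linear solve.
#' @param max_depth_m study-area depth cut-off.
#' @param seed master seed; all stage streams derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = grid_spec(5, 31, 0.15, 100, 100),
                            truth = truth_params(),
                            n_survey_stations = 2500,
                            n_presence_only = 60,
                            presence_only_regions = NULL,
                            block_size_km = 250,
                            n_folds = 5, n_repeats = 30,
                            algorithms = c("gam", "rf"),
                            k_max = 4, rf_trees = 500,
                            n_permutations = 10,
                            response_curves = TRUE,
                            curve_points = 100,
                            curve_background_max = 300,
                            buffer_km = 20, occ_threshold = 0.5,
                            krige_max_points = 1500,
                            max_depth_m = 2000,
                            seed = 1L) {
  if (is.null(presence_only_regions))
    presence_only_regions <- default_presence_only_regions(grid)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: seascape generation, occurrence
#' sampling, pseudo-absence implantation, aggregation, predictor
#' extraction, repeated spatial-block cross-validation, quartile
#' retention, ensemble suitability and threshold, uncertainty surfaces
#' (calibration, algorithm disagreement, kriged model-observation
#' comparison), change/refugia classification within the study area, and
#' the fishing-risk overlay on observed, suitable and refugial
#' footprints. Returns every intermediate product plus a manifest of
#' record counts and summary metrics; deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; if given, rasters (.asc), tables
#'   (.csv) and the manifest (.json) are written there.
#' @return list with the pipeline products and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  cfg <- config
  sea <- generate_seascape(cfg$grid, cfg$truth, seed = cfg$seed)
  design <- survey_design(cfg$n_survey_stations, cfg$presence_only_regions,
                          cfg$n_presence_only, seed = cfg$seed)
  occ <- sample_occurrences(sea$truth, sea$present$layers$bathymetry, design)
  occ_pa <- add_pseudo_absences(occ, cfg$presence_only_regions,
                                sea$present$layers$bathymetry,
                                seed = cfg$seed)
  agg <- aggregate_to_grid(occ_pa, cfg$grid, seed = cfg$seed)
  dataset <- extract_predictors(agg, sea$present)
  runs <- run_cross_validation(
    dataset, list(present = sea$present, future = sea$future),
    n_folds = cfg$n_folds, n_repeats = cfg$n_repeats,
    algorithms = cfg$algorithms, seed = cfg$seed,
    block_size_km = cfg$block_size_km, k_max = cfg$k_max,
    rf_trees = cfg$rf_trees, n_permutations = cfg$n_permutations,
    response_curves = cfg$response_curves,
    curve_points = cfg$curve_points,
    curve_background_max = cfg$curve_background_max)
  retained <- retain_models(runs)
  suit_p <- ensemble_suitability(retained, "present")
  suit_f <- ensemble_suitability(retained, "future")
  thr <- ensemble_threshold(suit_p, dataset)
  bin_p <- binarize_ensemble(suit_p, thr)
  bin_f <- binarize_ensemble(suit_f, thr)
  bathy <- sea$present$layers$bathymetry
  change <- classify_change(mask_study_area(bin_p, bathy, cfg$max_depth_m),
                            mask_study_area(bin_f, bathy, cfg$max_depth_m))
  change_sum <- habitat_change_summary(change)
  calib_p <- calibration_uncertainty(retained, "present")
  disagree <- algorithm_disagreement(retained, dataset)
  survey <- occ_pa[occ_pa$source == "survey", , drop = FALSE]
  krig_in <- if (nrow(survey) > cfg$krige_max_points)
    survey[with_seed(derive_seed(cfg$seed, 8L),
                     sample.int(nrow(survey), cfg$krige_max_points)), ]
  else survey
  kriged <- krige_occurrence(krig_in, cfg$grid, buffer_km = cfg$buffer_km,
                             seed = cfg$seed)
  agreement <- observation_agreement(bin_p, kriged, cfg$occ_threshold)
  observed <- binarize_layer(kriged, cfg$occ_threshold)
  rf_code <- attr(change$map, "classes")["refugia"]
  refugia <- raster_layer(
    cfg$grid,
    matrix(ifelse(is.na(change$map$values), NA_real_,
                  as.numeric(change$map$values == rf_code)),
           cfg$grid$n_rows, cfg$grid$n_cols),
    "refugia", "0/1")
  risk <- risk_levels(sea$fishing)
  overlays <- list(
    observed = overlay_risk(risk, observed, sea$regions),
    suitable = overlay_risk(risk, mask_study_area(bin_p, bathy,
                                                  cfg$max_depth_m),
                            sea$regions),
    refugia = overlay_risk(risk, refugia, sea$regions))
  met <- runs_metrics(successful_runs(runs))
  manifest <- list(
    seed = cfg$seed,
    n_occurrence_records = nrow(occ),
    n_with_pseudo_absences = nrow(occ_pa),
    n_aggregated = nrow(dataset),
    n_aggregated_presences = sum(dataset$detected == 1),
    n_records_dropped_nodata = attr(dataset, "n_dropped"),
    n_model_runs = length(runs),
    n_successful_runs = length(successful_runs(runs)),
    n_retained = length(retained),
    cv_auc_mean = mean(met$auc), cv_auc_sd = stats::sd(met$auc),
    cv_tss_mean = mean(met$tss), cv_tss_sd = stats::sd(met$tss),
    cv_sensitivity_mean = mean(met$sensitivity),
    cv_specificity_mean = mean(met$specificity),
    ensemble_threshold = thr,
    loss_pct = change_sum$loss_pct, gain_pct = change_sum$gain_pct,
    refugia_pct = change_sum$refugia_pct,
    areas_km2 = as.list(change_sum$areas_km2),
    risk_edges_h = as.list(stats::setNames(risk$edges,
                                           c("q1", "q2", "q3"))))
  result <- list(config = cfg, seascape = sea, occurrences = occ_pa,
                 dataset = dataset, runs = runs, retained = retained,
                 suitability_present = suit_p, suitability_future = suit_f,
                 ensemble_threshold = thr,
                 present_binary = bin_p, future_binary = bin_f,
                 change = change, change_summary = change_sum,
                 calibration = calib_p, disagreement = disagree,
                 kriged = kriged, agreement = agreement,
                 risk = risk, overlays = overlays, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (nm in names(result$seascape$present$layers))
    write_raster(result$seascape$present$layers[[nm]],
                 p(paste0(nm, ".asc")))
  write_raster(result$seascape$future$layers$temperature,
               p("temperature_rcp85.asc"))
  write_raster(result$suitability_present, p("suitability_present.asc"))
  write_raster(result$suitability_future, p("suitability_future.asc"))
  write_raster(result$change$map, p("habitat_change.asc"))
  write_raster(result$calibration, p("calibration_uncertainty.asc"))
  write_raster(result$disagreement, p("algorithm_disagreement.asc"))
  write_raster(result$kriged, p("kriged_occurrence.asc"))
  write_raster(result$risk$map, p("fishing_risk.asc"))
  utils::write.csv(result$occurrences, p("occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(runs_metrics(result$runs), p("run_metrics.csv"),
                   row.names = FALSE)
  for (nm in names(result$overlays))
    utils::write.csv(result$overlays[[nm]],
                     p(paste0("overlay_", nm, ".csv")), row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
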