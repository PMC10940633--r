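#' Repeated spatial-block cross-validation of the two learners
#'
#' The workhorse of the ensemble: for every repeat a fresh random
#' assignment of the 250-km spatial blocks to `n_folds` folds, and for
#' every (repeat, fold, algorithm) one model fitted on the out-of-fold
#' records and evaluated on the held-out fold. Each run records its
#' held-out AUC, TSS, sensitivity, specificity and TSS-optimal threshold,
#' the present-day and future probability maps binarised at that
#' threshold (the same threshold for both scenarios), and optionally
#' permutation importances and partial-dependence response curves.
#'
#' A fold whose held-out records are single-class cannot be evaluated;
#' such a run is recorded as failed with a reason and excluded from the
#' returned successful runs' statistics downstream.
#'
#' @param dataset model-ready dataset from [extract_predictors()].
#' @param stacks list with elements `present` and `future`
#'   ([predictor_stack()]s on the working grid).
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 30).
#' @param algorithms subset of `c("gam", "rf")`.
#' @param seed master seed; every random element derives from it.
#' @param block_size_km spatial block side (default 250 km).
#' @param k_max GAM basis cap (default 4).
#' @param rf_trees trees per forest (default 500).
#' @param n_permutations importance permutations per predictor (0 skips
#'   importances).
#' @param response_curves compute per-run response curves?
#' @param curve_points points per curve.
#' @param curve_background_max background rows used for the
#'   partial-dependence average (training rows are subsampled to this
#'   cap; curves average over the cap, keeping run cost bounded).
#' @return object of class `sdm_runs`: list of run records.
#' @export
run_cross_validation <- function(dataset, stacks, n_folds = 5,
                                 n_repeats = 30,
                                 algorithms = c("gam", "rf"), seed = 1L,
                                 block_size_km = 250, k_max = 4,
                                 rf_trees = 500, n_permutations = 10,
                                 response_curves = TRUE, curve_points = 100,
                                 curve_background_max = 300) {
  algorithms <- match.arg(algorithms, c("gam", "rf"), several.ok = TRUE)
  predictors <- attr(dataset, "predictors")
  if (is.null(predictors)) stop("dataset lacks predictors; run extract_predictors()")
  blocks <- build_blocks(dataset, block_size_km)
  runs <- vector("list", n_repeats * n_folds * length(algorithms))
  idx <- 0L
  for (rep_i in seq_len(n_repeats)) {
    fa <- assign_folds(blocks, n_folds, seed = derive_seed(seed, 100 + rep_i))
    for (fold_i in seq_len(n_folds)) {
      train <- dataset[fa$fold != fold_i, , drop = FALSE]
      test <- dataset[fa$fold == fold_i, , drop = FALSE]
      for (alg in algorithms) {
        idx <- idx + 1L
        run <- list(run_id = idx, algorithm = alg, repeat_id = rep_i,
                    fold_id = fold_i, training_size = nrow(train),
                    status = "ok", reason = NA_character_)
        bad <- if (length(unique(test$detected)) < 2) {
          "single-class test fold"
        } else if (sum(train$detected == 1) < 2 ||
                   sum(train$detected == 0) < 2) {
          "degenerate training fold"
        } else NA_character_
        if (!is.na(bad)) {
          run$status <- "failed"; run$reason <- bad
          runs[[idx]] <- run
          next
        }
        model <- tryCatch(
          if (alg == "gam") fit_gam(train, predictors, k_max = k_max)
          else fit_rf(train, predictors, n_trees = rf_trees,
                      seed = derive_seed(seed, 1000L + idx)),
          error = function(e) e)
        if (inherits(model, "error")) {
          run$status <- "failed"; run$reason <- conditionMessage(model)
          runs[[idx]] <- run
          next
        }
        pred_test <- predict(model, test)
        thr <- optimal_tss_threshold(test$detected, pred_test)
        cm <- confusion_metrics(test$detected, pred_test, thr)
        run$evaluation <- list(auc = roc_auc(test$detected, pred_test),
                               tss = cm$tss, sensitivity = cm$sensitivity,
                               specificity = cm$specificity, threshold = thr)
        pm <- predict_map(model, stacks$present)
        fm <- predict_map(model, stacks$future)
        run$present_binary <- binarize_layer(pm, thr)
        run$future_binary <- binarize_layer(fm, thr)
        if (n_permutations > 0)
          run$importance <- permutation_importance(
            model, test, n_permutations,
            seed = derive_seed(seed, 2000L + idx))
        if (response_curves) {
          bg <- train
          if (nrow(bg) > curve_background_max)
            bg <- bg[with_seed(derive_seed(seed, 3000L + idx),
                               sample.int(nrow(bg), curve_background_max)), ]
          run$curves <- lapply(stats::setNames(predictors, predictors),
                               function(pn) response_curve(
                                 model, pn, bg, n_points = curve_points))
        }
        runs[[idx]] <- run
      }
    }
  }
  structure(runs, class = "sdm_runs",
            predictors = predictors, seed = seed)
}

binarize_layer <- function(layer, threshold) {
  v <- layer$values
  v[!is.na(v)] <- as.numeric(v[!is.na(v)] >= threshold)
  raster_layer(layer$grid, v, paste0(layer$name, "_binary"), "0/1")
}

#' @export
print.sdm_runs <- function(x, ...) {
  ok <- successful_runs(x)
  cat(sprintf("<sdm_runs> %d runs (%d successful)\n", length(x), length(ok)))
  if (length(ok)) {
    aucs <- vapply(ok, function(r) r$evaluation$auc, 0)
    cat(sprintf("  AUC mean %.3f sd %.3f\n", mean(aucs), stats::sd(aucs)))
  }
  invisible(x)
}

#' Successful runs of a CV result
#'
#' @param runs an `sdm_runs` object.
#' @return the subset of runs with `status == "ok"`, class preserved.
#' @export
successful_runs <- function(runs) {
  structure(Filter(function(r) identical(r$status, "ok"), runs),
            class = "sdm_runs", predictors = attr(runs, "predictors"))
}

#' Run-level metrics as a table
#'
#' @param runs an `sdm_runs` object.
#' @return data.frame keyed by (run_id, repeat, fold, algorithm) with the
#'   held-out metrics; failed runs carry NA metrics and their reason.
#' @export
runs_metrics <- function(runs) {
  do.call(rbind, lapply(runs, function(r) {
    ev <- r$evaluation
    data.frame(run_id = r$run_id, repeat_id = r$repeat_id,
               fold_id = r$fold_id, algorithm = r$algorithm,
               status = r$status,
               auc = if (is.null(ev)) NA_real_ else ev$auc,
               tss = if (is.null(ev)) NA_real_ else ev$tss,
               sensitivity = if (is.null(ev)) NA_real_ else ev$sensitivity,
               specificity = if (is.null(ev)) NA_real_ else ev$specificity,
               threshold = if (is.null(ev)) NA_real_ else ev$threshold,
               reason = r$reason, row.names = NULL)
  }))
}

#' Discard the first AUC quartile of model runs
#'
#' The 25% poorest models by held-out AUC are discarded so the ensemble is
#' not dragged down by folds whose training data could not capture the
#' habitat signal. Operationally, exactly `floor(n/4)` lowest-AUC runs are
#' removed (ties broken by run id), so 300 runs retain exactly 225
#' regardless of AUC ties. Failed runs are excluded beforehand and the
#' quartile taken over the successful ones.
#'
#' @param runs an `sdm_runs` object.
#' @return the retained runs (`sdm_runs`), with attribute
#'   `"discarded_ids"`.
#' @export
retain_models <- function(runs) {
  ok <- successful_runs(runs)
  n <- length(ok)
  if (n < 4) stop("need at least 4 successful runs to apply the quartile rule")
  aucs <- vapply(ok, function(r) r$evaluation$auc, 0)
  ids <- vapply(ok, function(r) r$run_id, 0L)
  ord <- order(aucs, ids)
  drop <- ord[seq_len(n %/% 4L)]
  keep <- sort(setdiff(seq_len(n), drop))
  structure(ok[keep], class = "sdm_runs",
            predictors = attr(runs, "predictors"),
            discarded_ids = ids[drop])
}

#' Ensemble habitat suitability map
#'
#' The per-cell arithmetic mean of the retained runs' binary maps: the
#' fraction of retained models that call the cell suitable. Averaging
#' binaries rather than probabilities keeps the two algorithms' different
#' probability calibrations from biasing the index.
#'
#' @param retained retained runs ([retain_models()]).
#' @param scenario `"present"` or `"future"`.
#' @return [raster_layer()] in \[0, 1\]; nodata where any retained map is
#'   nodata.
#' @export
ensemble_suitability <- function(retained, scenario = c("present", "future")) {
  scenario <- match.arg(scenario)
  if (length(retained) < 1) stop("no retained runs")
  key <- paste0(scenario, "_binary")
  maps <- lapply(retained, `[[`, key)
  g <- maps[[1]]$grid
  for (m in maps) stop_if_grid_mismatch(g, m, "binary maps")
  s <- Reduce(`+`, lapply(maps, `[[`, "values"))
  raster_layer(g, s / length(maps),
               paste0("ensemble_suitability_", scenario), "fraction")
}

#' Ensemble binarisation threshold
#'
#' The ensemble suitability (a model-vote fraction) is evaluated at every
#' aggregated record and the TSS-optimal threshold over those values is
#' returned; it converts the ensemble index into the presence/absence
#' maps used for change classification.
#'
#' @param suitability present-day ensemble suitability
#'   ([ensemble_suitability()]).
#' @param dataset the aggregated dataset (with `cell` and `detected`).
#' @return threshold in \[0, 1\].
#' @export
ensemble_threshold <- function(suitability, dataset) {
  vals <- layer_at_cells(suitability, dataset$cell)
  ok <- !is.na(vals)
  if (!all(ok))
    warning(sum(!ok), " record(s) on nodata suitability cells ignored")
  optimal_tss_threshold(dataset$detected[ok], vals[ok])
}
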