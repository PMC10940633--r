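# a compact CV setting shared by these tests
cv_fixture <- function(seed = 11) {
  sd <- small_dataset(seed = seed)
  list(dataset = sd$dataset,
       stacks = list(present = sd$sea$present, future = sd$sea$future))
}

test_that("the CV engine produces one run per repeat x fold x algorithm", {
  fx <- cv_fixture()
  runs <- run_cross_validation(fx$dataset, fx$stacks, n_folds = 2,
                               n_repeats = 1, algorithms = "gam",
                               seed = 1, block_size_km = 150,
                               n_permutations = 0, response_curves = FALSE)
  expect_length(runs, 2)
  met <- runs_metrics(runs)
  expect_setequal(met$fold_id, 1:2)
  expect_true(all(met$algorithm == "gam"))
  # thresholds verify the TSS identity of their own evaluation
  ok <- met[met$status == "ok", ]
  expect_equal(ok$tss, ok$sensitivity + ok$specificity - 1,
               tolerance = 1e-12)
})

test_that("the CV engine is deterministic in its master seed", {
  fx <- cv_fixture()
  r1 <- run_cross_validation(fx$dataset, fx$stacks, n_folds = 3,
                             n_repeats = 2, algorithms = c("gam", "rf"),
                             seed = 5, block_size_km = 150, rf_trees = 50,
                             n_permutations = 1, response_curves = FALSE)
  r2 <- run_cross_validation(fx$dataset, fx$stacks, n_folds = 3,
                             n_repeats = 2, algorithms = c("gam", "rf"),
                             seed = 5, block_size_km = 150, rf_trees = 50,
                             n_permutations = 1, response_curves = FALSE)
  expect_equal(runs_metrics(r1), runs_metrics(r2))
  expect_identical(r1[[3]]$present_binary$values,
                   r2[[3]]$present_binary$values)
  expect_length(r1, 2 * 3 * 2)
})

test_that("binary maps are the run's own thresholded probability maps", {
  fx <- cv_fixture()
  runs <- run_cross_validation(fx$dataset, fx$stacks, n_folds = 2,
                               n_repeats = 1, algorithms = "gam", seed = 2,
                               block_size_km = 150, n_permutations = 0,
                               response_curves = FALSE)
  r <- successful_runs(runs)[[1]]
  v <- r$present_binary$values
  expect_true(all(v %in% c(0, 1) | is.na(v)))
  expect_true(r$evaluation$threshold >= 0 && r$evaluation$threshold <= 1)
})

test_that("quartile retention drops exactly the floor(n/4) worst by AUC", {
  mk_run <- function(id, auc) list(run_id = id, status = "ok",
                                   evaluation = list(auc = auc))
  four <- structure(lapply(1:4, function(i)
    mk_run(i, c(0.6, 0.9, 0.7, 0.8)[i])), class = "sdm_runs")
  kept <- retain_models(four)
  expect_length(kept, 3)
  expect_false(0.6 %in% vapply(kept, function(r) r$evaluation$auc, 0))

  withr::with_seed(51, {
    aucs <- runif(8, 0.5, 1)
    eight <- structure(lapply(1:8, function(i) mk_run(i, aucs[i])),
                       class = "sdm_runs")
    kept8 <- retain_models(eight)
    # sort oracle: drop the two lowest
    oracle_keep <- sort(order(aucs)[-(1:2)])
    expect_equal(vapply(kept8, function(r) r$run_id, 0L), oracle_keep)
  })

  # failed runs are excluded before the quartile is taken
  with_failed <- structure(c(four, list(list(run_id = 5, status = "failed",
                                             evaluation = NULL))),
                           class = "sdm_runs")
  expect_length(retain_models(with_failed), 3)
  expect_error(retain_models(structure(four[1:3], class = "sdm_runs")),
               "at least 4")
})

test_that("retention tie-break on equal AUCs removes the lowest run ids", {
  mk_run <- function(id, auc) list(run_id = id, status = "ok",
                                   evaluation = list(auc = auc))
  tied <- structure(lapply(1:8, function(i) mk_run(i, 0.75)),
                    class = "sdm_runs")
  kept <- retain_models(tied)
  expect_equal(vapply(kept, function(r) r$run_id, 0L), 3:8)
})

test_that("ensemble suitability is the mean of binary maps", {
  g <- grid_spec(0, 40, 0.1, 3, 3)
  mk <- function(vals) list(present_binary = raster_layer(
    g, matrix(vals, 3, 3, byrow = TRUE)), status = "ok")
  runs <- structure(list(mk(rep(1, 9)), mk(rep(0, 9)), mk(rep(1, 9))),
                    class = "sdm_runs")
  es <- ensemble_suitability(runs, "present")
  expect_equal(es$values[1, 1], 2 / 3)
  # invariant to run ordering
  es2 <- ensemble_suitability(structure(rev(runs), class = "sdm_runs"),
                              "present")
  expect_equal(es$values, es2$values)
  # all-ones cell
  runs1 <- structure(list(mk(rep(1, 9)), mk(rep(1, 9))), class = "sdm_runs")
  expect_true(all(ensemble_suitability(runs1, "present")$values == 1))
})

test_that("the ensemble threshold maximises TSS over the vote fractions", {
  g <- grid_spec(0, 40, 0.1, 5, 10)
  withr::with_seed(52, {
    suit <- raster_layer(g, matrix(sample(0:4, 50, TRUE) / 4, 5, 10))
    cells <- sample(1:50, 50)
    det <- rbinom(50, 1, layer_at_cells_test(suit, cells) * 0.8 + 0.1)
    det[1:2] <- c(0, 1)
    ds <- data.frame(cell = cells, detected = det)
    thr <- ensemble_threshold(suit, ds)
    # support: a quartile fraction, 0 or 1
    expect_true(thr %in% c(0, 1, (0:4) / 4))
    achieved <- confusion_metrics(det, layer_at_cells_test(suit, cells),
                                  thr)$tss
    expect_equal(achieved, best_tss_gridscan(det,
                                             layer_at_cells_test(suit, cells)),
                 tolerance = 1e-12)
  })
})

test_that("a perfect ensemble yields its smallest positive vote as threshold", {
  g <- grid_spec(0, 40, 0.1, 2, 5)
  suit <- raster_layer(g, matrix(c(0, 0, 0, 0.6, 1, 1, 0, 0, 0.6, 0),
                                 2, 5, byrow = TRUE))
  ds <- data.frame(cell = 1:10,
                   detected = as.integer(layer_at_cells_test(suit, 1:10) > 0))
  expect_equal(ensemble_threshold(suit, ds), 0.6)
})
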