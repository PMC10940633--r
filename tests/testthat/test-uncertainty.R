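mk_binary_runs <- function(cell_votes, g = grid_spec(0, 40, 0.1, 1, 1)) {
  # one-cell rasters carrying the given votes
  structure(lapply(cell_votes, function(v)
    list(present_binary = raster_layer(g, matrix(v, 1, 1)), status = "ok")),
    class = "sdm_runs")
}

test_that("calibration ratio matches hand-computed mean/sd", {
  # {1,1,0,0,1}: mean 0.6, population sd sqrt(0.24), ratio ~ 1.2247
  runs <- mk_binary_runs(c(1, 1, 0, 0, 1))
  r <- calibration_uncertainty(runs, "present")
  expect_equal(r$values[1, 1], 0.6 / sqrt(0.24), tolerance = 1e-12)

  # half ones, half zeros: ratio exactly 1
  expect_equal(calibration_uncertainty(
    mk_binary_runs(c(1, 0, 1, 0)), "present")$values[1, 1], 1)

  # full agreement: sd 0 -> nodata, counted
  agree <- calibration_uncertainty(mk_binary_runs(c(1, 1, 1)), "present")
  expect_true(is.na(agree$values[1, 1]))
  expect_equal(attr(agree, "n_sd_zero"), 1)
  expect_error(calibration_uncertainty(mk_binary_runs(1), "present"),
               "at least 2")
})

test_that("calibration ratio depends only on the multiset of votes", {
  a <- calibration_uncertainty(mk_binary_runs(c(1, 0, 0, 1, 1)), "present")
  b <- calibration_uncertainty(mk_binary_runs(c(0, 1, 1, 1, 0)), "present")
  expect_equal(a$values, b$values)
  expect_true(all(a$values >= 0, na.rm = TRUE))
})

test_that("algorithm disagreement classifies the sub-ensemble cross-table", {
  sd <- small_dataset(seed = 14)
  runs <- run_cross_validation(
    sd$dataset, list(present = sd$sea$present, future = sd$sea$future),
    n_folds = 3, n_repeats = 2, algorithms = c("gam", "rf"), seed = 3,
    block_size_km = 150, rf_trees = 50, n_permutations = 0,
    response_curves = FALSE)
  kept <- retain_models(runs)
  dis <- algorithm_disagreement(kept, sd$dataset)
  cls <- attr(dis, "classes")
  expect_setequal(names(cls),
                  c("both_suitable", "both_unsuitable", "gam_only",
                    "rf_only"))
  v <- dis$values[!is.na(dis$values)]
  expect_true(all(v %in% cls))
  # identical sub-ensembles cannot disagree: feed only GAM runs twice
  gam_only_runs <- structure(
    Filter(function(r) r$algorithm == "gam", kept), class = "sdm_runs")
  fake_rf <- lapply(gam_only_runs, function(r) { r$algorithm <- "rf"; r })
  both <- structure(c(gam_only_runs, fake_rf), class = "sdm_runs")
  dis2 <- algorithm_disagreement(both, sd$dataset)
  v2 <- dis2$values[!is.na(dis2$values)]
  expect_true(all(v2 %in% cls[c("both_suitable", "both_unsuitable")]))
  expect_error(algorithm_disagreement(gam_only_runs, sd$dataset), "no retained rf")
})

test_that("variogram models evaluate and validate", {
  vm <- variogram_model("spherical", nugget = 0.05, sill = 0.25,
                        range_km = 100)
  expect_equal(variogram_values(vm, 0), 0)
  expect_equal(variogram_values(vm, 1e9), 0.25)   # sill beyond the range
  h <- c(10, 50, 99)
  expect_true(all(diff(variogram_values(vm, h)) > 0))
  expect_error(variogram_model("spherical", -0.1, 0.2, 10), "nugget")
  expect_error(variogram_model("spherical", 0.3, 0.2, 10), "sill")
})

test_that("ordinary kriging reproduces constants and interpolates exactly", {
  g <- grid_spec(0, 40, 0.05, 12, 12)
  vm <- variogram_model("spherical", nugget = 0, sill = 0.2, range_km = 60)
  recs <- data.frame(lon = c(0.12, 0.31, 0.44, 0.25),
                     lat = c(40.11, 40.42, 40.21, 40.33),
                     detected = c(0.7, 0.7, 0.7, 0.7), source = "survey")
  k <- krige_occurrence(recs, g, vm, buffer_km = 50)
  expect_equal(k$values[!is.na(k$values)],
               rep(0.7, sum(!is.na(k$values))), tolerance = 1e-9)

  # exact interpolation at data cells with zero nugget
  recs2 <- data.frame(lon = cell_lons(g)[c(2, 7, 10)],
                      lat = cell_lats(g)[c(3, 8, 5)],
                      detected = c(1, 0, 1), source = "survey")
  k2 <- krige_occurrence(recs2, g, vm, buffer_km = 200)
  loc <- locate_cells(g, recs2$lon, recs2$lat)
  expect_equal(layer_at_cells_test(k2, loc$cell), recs2$detected,
               tolerance = 1e-8)
})

test_that("kriging weights solve the hand-built 3-point system", {
  g <- grid_spec(0, 40, 0.05, 10, 10)
  vm <- variogram_model("spherical", nugget = 0.02, sill = 0.3,
                        range_km = 80)
  pts <- data.frame(lon = c(0.08, 0.33, 0.19), lat = c(40.07, 40.22, 40.41),
                    detected = c(1, 0, 1), source = "survey")
  target <- c(cell_lons(g)[5], cell_lats(g)[5])  # (0.225, 40.275)
  D <- geosphere::distm(rbind(as.matrix(pts[1:2]), target)) / 1000
  G <- variogram_values(vm, D[1:3, 1:3])
  A <- rbind(cbind(G, 1), c(1, 1, 1, 0))
  b <- c(variogram_values(vm, D[1:3, 4]), 1)
  w <- solve(A, b)
  expect_equal(sum(w[1:3]), 1, tolerance = 1e-12)   # unbiasedness
  oracle <- sum(w[1:3] * pts$detected)
  k <- krige_occurrence(pts, g, vm, buffer_km = 100)
  expect_equal(k$values[5, 5], oracle, tolerance = 1e-10)
})

test_that("the kriging buffer masks distant cells and duplicates average", {
  g <- grid_spec(0, 40, 0.05, 40, 40)   # 2 x 2 degrees
  vm <- variogram_model("spherical", nugget = 0.01, sill = 0.2,
                        range_km = 50)
  pts <- data.frame(lon = c(0.1, 0.1, 0.12), lat = c(40.1, 40.1, 40.12),
                    detected = c(1, 0, 1), source = "survey")
  k <- krige_occurrence(pts, g, vm, buffer_km = 20)
  lon <- rep(cell_lons(g), times = 40); lat <- rep(cell_lats(g), each = 40)
  dmin <- apply(geosphere::distm(cbind(lon, lat),
                                 unique(as.matrix(pts[1:2]))) / 1000, 1, min)
  vals <- layer_at_cells_test(k, seq_along(lon))
  expect_true(all(is.na(vals[dmin > 20])))
  expect_true(all(!is.na(vals[dmin <= 19.9])))
  # an interpolated 0/1 field never leaves [0, 1]
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  expect_error(krige_occurrence(pts[1:2, ], g, vm), "at least 3")
  # pseudo-absences are excluded before kriging
  pts_pa <- rbind(pts, data.frame(lon = 0.5, lat = 40.5, detected = 0,
                                  source = "pseudo_absence"))
  k2 <- krige_occurrence(pts_pa, g, vm, buffer_km = 20)
  expect_equal(k2$values, k$values)
})

test_that("a fitted variogram recovers generated spatial structure", {
  sd <- small_dataset(seed = 15, n_stations = 300)
  sv <- sd$dataset
  vm <- fit_variogram(data.frame(lon = sv$lon, lat = sv$lat,
                                 detected = sv$detected), seed = 1)
  expect_s3_class(vm, "variogram_model")
  expect_gte(vm$sill, vm$nugget)
  expect_gt(vm$range_km, 0)
})

test_that("observation agreement covers the exhaustive 2x2 plus unsurveyed", {
  g <- grid_spec(0, 40, 0.1, 1, 5)
  model <- raster_layer(g, matrix(c(1, 1, 0, 0, 1), 1, 5))
  kriged <- raster_layer(g, matrix(c(0.8, 0.2, 0.1, 0.9, NA), 1, 5))
  agr <- observation_agreement(model, kriged, occ_threshold = 0.5)
  cls <- attr(agr, "classes")
  expect_equal(unname(agr$values[1, ]),
               unname(c(cls["agreement_suitable"],
                        cls["disagreement_suitable"],
                        cls["agreement_unsuitable"],
                        cls["disagreement_unsuitable"],
                        cls["unsurveyed"])))
  # class areas partition the surveyed footprint
  a <- cell_area(g)$values
  surveyed <- sum(a[!is.na(kriged$values)])
  by_class <- sum(a[!is.na(agr$values) &
                      agr$values != cls["unsurveyed"]])
  expect_equal(by_class, surveyed)
  # identical model and binarised surface -> no disagreement classes
  same <- observation_agreement(model,
                                raster_layer(g, model$values), 0.5)
  v <- same$values[!is.na(same$values)]
  expect_false(any(v %in% cls[c("disagreement_suitable",
                                "disagreement_unsuitable")]))
})
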