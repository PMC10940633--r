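#' Calibration uncertainty of the ensemble
#'
#' Per-cell mean of the retained binary maps divided by their standard
#' deviation (population form, divisor n): a signal-to-noise ratio of the
#' ensemble vote. High values mean the models agree regardless of the
#' spatial fold assignment; cells where all models agree exactly (sd = 0)
#' are nodata and counted in the `"n_sd_zero"` attribute.
#'
#' @param retained retained runs ([retain_models()]), at least 2.
#' @param scenario `"present"` or `"future"`.
#' @return [raster_layer()] of mean/sd ratios.
#' @export
calibration_uncertainty <- function(retained,
                                    scenario = c("present", "future")) {
  scenario <- match.arg(scenario)
  if (length(retained) < 2) stop("need at least 2 retained runs")
  key <- paste0(scenario, "_binary")
  mats <- lapply(retained, function(r) r[[key]]$values)
  g <- retained[[1]][[key]]$grid
  n <- length(mats)
  m1 <- Reduce(`+`, mats) / n
  m2 <- Reduce(`+`, lapply(mats, function(x) x^2)) / n
  sdp <- sqrt(pmax(m2 - m1^2, 0))
  ratio <- m1 / sdp
  zero <- !is.na(sdp) & sdp == 0
  ratio[zero] <- NA_real_
  out <- raster_layer(g, ratio, paste0("calibration_", scenario), "mean/sd")
  attr(out, "n_sd_zero") <- sum(zero)
  out
}

#' Where the two algorithms disagree
#'
#' The ensemble methodology (mean of binaries, own TSS-optimal threshold
#' on the aggregated dataset, binarisation) is applied separately to the
#' retained GAMs and the retained random forests; the two binary
#' sub-ensembles are then cross-tabulated per cell.
#'
#' @param retained retained runs with at least one run per algorithm.
#' @param dataset the aggregated dataset (threshold calibration).
#' @param scenario `"present"` or `"future"`. Thresholds are always
#'   calibrated on the present-day sub-ensembles, as for the combined
#'   ensemble, and applied to the chosen scenario.
#' @return categorical [raster_layer()] with integer codes and a
#'   `"classes"` attribute: 1 both_suitable, 2 both_unsuitable,
#'   3 gam_only, 4 rf_only.
#' @export
algorithm_disagreement <- function(retained, dataset,
                                   scenario = c("present", "future")) {
  scenario <- match.arg(scenario)
  sub <- function(alg) {
    rs <- structure(Filter(function(r) r$algorithm == alg, retained),
                    class = "sdm_runs")
    if (length(rs) == 0) stop("no retained ", alg, " runs")
    thr <- ensemble_threshold(ensemble_suitability(rs, "present"), dataset)
    suit <- ensemble_suitability(rs, scenario)
    binarize_layer(suit, thr)
  }
  bg <- sub("gam"); br <- sub("rf")
  gv <- bg$values; rv <- br$values
  code <- matrix(NA_real_, nrow(gv), ncol(gv))
  code[gv == 1 & rv == 1] <- 1
  code[gv == 0 & rv == 0] <- 2
  code[gv == 1 & rv == 0] <- 3
  code[gv == 0 & rv == 1] <- 4
  out <- raster_layer(bg$grid, code, "algorithm_disagreement", "class")
  attr(out, "classes") <- c(both_suitable = 1, both_unsuitable = 2,
                            gam_only = 3, rf_only = 4)
  out
}

#' Fit a variogram model to survey occurrences
#'
#' Empirical semivariogram of the 0/1 detections over great-circle
#' distance, fitted by weighted least squares (Cressie weights N(h) /
#' gamma(h)^2) with a spherical or exponential model.
#'
#' @param records survey records (`lon`, `lat`, `detected`).
#' @param kind `"spherical"` or `"exponential"`.
#' @param n_bins distance bins up to half the maximum pairwise distance.
#' @param max_points pairwise computation is capped by subsampling to
#'   this many records (deterministic given `seed`).
#' @param seed integer seed for the subsample.
#' @return object of class `variogram_model`: list(kind, nugget, sill,
#'   range_km), with the empirical variogram as attribute.
#' @export
fit_variogram <- function(records, kind = c("spherical", "exponential"),
                          n_bins = 15, max_points = 500, seed = 1L) {
  kind <- match.arg(kind)
  if (nrow(records) > max_points)
    records <- records[with_seed(derive_seed(seed, 7L),
                                 sample.int(nrow(records), max_points)), ]
  xy <- as.matrix(records[c("lon", "lat")])
  D <- geosphere::distm(xy) / 1000
  z <- records$detected
  dz2 <- 0.5 * outer(z, z, `-`)^2
  ut <- upper.tri(D)
  d <- D[ut]; sv <- dz2[ut]
  dmax <- max(d) / 2
  br <- seq(0, dmax, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  emp <- data.frame(
    h = tapply(d, bin, mean),
    gamma = tapply(sv, bin, mean),
    n = as.integer(table(bin)))
  emp <- emp[emp$n > 0 & !is.na(emp$gamma), ]
  s2 <- stats::var(z)
  obj <- function(par) {
    g <- variogram_values(list(kind = kind, nugget = par[1],
                               sill = par[1] + par[2], range_km = par[3]),
                          emp$h)
    sum(emp$n * (emp$gamma - g)^2 / pmax(g, 1e-8)^2)
  }
  fit <- stats::optim(c(0.1 * s2 + 1e-6, s2, dmax / 2), obj,
                      method = "L-BFGS-B",
                      lower = c(0, 1e-8, 1e-3),
                      upper = c(s2 * 2, s2 * 4, dmax * 4))
  vm <- variogram_model(kind, nugget = fit$par[1],
                        sill = fit$par[1] + fit$par[2],
                        range_km = fit$par[3])
  attr(vm, "empirical") <- emp
  vm
}

#' Construct a variogram model
#'
#' @param kind `"spherical"` or `"exponential"`.
#' @param nugget nugget semivariance (>= 0).
#' @param sill total sill (>= nugget, > 0).
#' @param range_km range parameter in km (> 0).
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(kind = c("spherical", "exponential"),
                            nugget, sill, range_km) {
  kind <- match.arg(kind)
  stopifnot(nugget >= 0, sill > 0, sill >= nugget, range_km > 0)
  structure(list(kind = kind, nugget = nugget, sill = sill,
                 range_km = range_km), class = "variogram_model")
}

#' Semivariance of a variogram model at distances
#'
#' @param vm a [variogram_model()].
#' @param h distances in km (gamma(0) = 0 by convention).
#' @return semivariances.
#' @export
variogram_values <- function(vm, h) {
  psill <- vm$sill - vm$nugget
  g <- if (vm$kind == "spherical") {
    hr <- pmin(h / vm$range_km, 1)
    vm$nugget + psill * (1.5 * hr - 0.5 * hr^3)
  } else {
    vm$nugget + psill * (1 - exp(-h / vm$range_km))
  }
  g[h == 0] <- 0
  g
}

#' Ordinary kriging of survey detections
#'
#' Interpolates the 0/1 survey detections (pseudo-absences excluded) onto
#' the grid by ordinary kriging: at each cell the prediction is a
#' weighted mean of the observations, the weights solving the
#' ordinary-kriging system built from the variogram; weights sum to one,
#' and with a zero nugget the surface interpolates the data exactly.
#' Predictions are clamped to the observed value range (negative weights
#' can overshoot it), the usual order-relation correction for a 0/1
#' variable.
#' Cells farther than `buffer_km` from every record are nodata — the
#' interpolated occurrence field is only meaningful near surveyed
#' corridors. Records sharing a location are averaged first so the
#' kriging matrix stays non-singular.
#'
#' @param records occurrence records; rows with
#'   `source == "pseudo_absence"` are dropped.
#' @param grid target [grid_spec()].
#' @param variogram a [variogram_model()], or NULL to fit one with
#'   [fit_variogram()].
#' @param buffer_km prediction mask radius (default 20).
#' @param seed seed passed to the variogram fit.
#' @return [raster_layer()] of interpolated detection probability.
#' @export
krige_occurrence <- function(records, grid, variogram = NULL,
                             buffer_km = 20, seed = 1L) {
  if (!is.null(records$source))
    records <- records[records$source != "pseudo_absence", , drop = FALSE]
  if (nrow(records) < 3) stop("need at least 3 survey records")
  # average duplicate locations
  key <- paste(records$lon, records$lat)
  z <- tapply(records$detected, key, mean)
  first <- !duplicated(key)
  xy <- as.matrix(records[first, c("lon", "lat")])
  z <- as.numeric(z[key[first]])
  n <- nrow(xy)
  if (is.null(variogram))
    variogram <- fit_variogram(records, seed = seed)
  G <- variogram_values(variogram, geosphere::distm(xy) / 1000)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  lon <- rep(cell_lons(grid), times = grid$n_rows)
  lat <- rep(cell_lats(grid), each = grid$n_cols)
  out <- rep(NA_real_, length(lon))
  chunk <- 2000L
  for (s in seq(1L, length(lon), by = chunk)) {
    e <- min(s + chunk - 1L, length(lon))
    Dc <- geosphere::distm(cbind(lon[s:e], lat[s:e]), xy) / 1000
    near <- apply(Dc, 1, min) <= buffer_km
    if (!any(near)) next
    B <- rbind(t(variogram_values(variogram, Dc[near, , drop = FALSE])),
               1)
    W <- solve(A, B)
    out[(s:e)[near]] <- as.numeric(crossprod(W[seq_len(n), , drop = FALSE],
                                             z))
  }
  # negative kriging weights can push predictions outside the observed
  # range; clamp to it (the usual order-relation correction for an
  # indicator variable)
  out <- pmin(pmax(out, min(z)), max(z))
  raster_layer(grid, matrix(out, grid$n_rows, grid$n_cols, byrow = TRUE),
               "kriged_occurrence", "probability")
}

#' Model-observation agreement map
#'
#' Compares the ensemble's binary suitability with the kriged occurrence
#' field inside the surveyed footprint (the kriging buffer): agreement
#' and disagreement are recorded separately for the suitable and
#' unsuitable sides, and everything outside the footprint is marked
#' unsurveyed.
#'
#' @param ensemble_binary binary suitability [raster_layer()].
#' @param kriged output of [krige_occurrence()] on the same grid.
#' @param occ_threshold kriged value at or above which a cell counts as
#'   an observed-presence area (default 0.5).
#' @return categorical [raster_layer()] with `"classes"` attribute:
#'   1 agreement_suitable, 2 disagreement_suitable,
#'   3 agreement_unsuitable, 4 disagreement_unsuitable, 5 unsurveyed.
#' @export
observation_agreement <- function(ensemble_binary, kriged,
                                  occ_threshold = 0.5) {
  stop_if_grid_mismatch(ensemble_binary, kriged)
  mb <- ensemble_binary$values; kv <- kriged$values
  code <- matrix(NA_real_, nrow(mb), ncol(mb))
  surveyed <- !is.na(kv)
  code[!surveyed & !is.na(mb)] <- 5
  occ <- surveyed & kv >= occ_threshold
  code[mb == 1 & occ] <- 1
  code[mb == 1 & surveyed & !occ] <- 2
  code[mb == 0 & surveyed & !occ] <- 3
  code[mb == 0 & occ] <- 4
  out <- raster_layer(ensemble_binary$grid, code,
                      "observation_agreement", "class")
  attr(out, "classes") <- c(agreement_suitable = 1,
                            disagreement_suitable = 2,
                            agreement_unsuitable = 3,
                            disagreement_unsuitable = 4,
                            unsurveyed = 5)
  out
}
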