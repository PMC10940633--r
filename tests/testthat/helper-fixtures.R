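# Shared fixture builders; everything is generated in code.

# a small raster with given values (vector filled row-major, row 1 north)
toy_layer <- function(values, n_rows, n_cols, lon_min = 0, lat_min = 40,
                      cell_size = 0.1, name = "toy") {
  g <- grid_spec(lon_min, lat_min, cell_size, n_rows, n_cols)
  raster_layer(g, matrix(values, n_rows, n_cols, byrow = TRUE), name = name)
}

# constant-layer predictor stack over a tiny grid
constant_stack <- function(vals = c(bathymetry = -600, slope = 2,
                                    temperature = 13.5, salinity = 38.6,
                                    current_velocity = 0.01),
                           n = 5) {
  g <- grid_spec(0, 40, 0.1, n, n)
  predictor_stack(lapply(as.list(vals), function(v)
    raster_layer(g, matrix(v, n, n))), scenario = "present")
}

# two-predictor logistic training table: detected ~ logistic(2 * x1),
# x2 pure noise
logistic_table <- function(n = 500, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    x2 <- stats::rnorm(n)
    d <- data.frame(detected = stats::rbinom(n, 1, stats::plogis(2 * x1)),
                    x1 = x1, x2 = x2)
    attr(d, "predictors") <- c("x1", "x2")
    d
  })
}

# a small model-ready dataset on a seascape, for CV-level tests
small_dataset <- function(seed = 11, n_stations = 400, grid_n = 50) {
  g <- grid_spec(5, 31, 0.3, grid_n, grid_n)
  sea <- generate_seascape(g, truth_params(), seed = seed)
  occ <- sample_occurrences(sea$truth, sea$present$layers$bathymetry,
                            survey_design(n_stations, list(), 0,
                                          seed = seed))
  agg <- aggregate_to_grid(occ, g, seed = seed)
  dataset <- extract_predictors(agg, sea$present)
  list(grid = g, sea = sea, dataset = dataset)
}

# training table over the five seascape predictors, with a temperature-
# and depth-driven response
small_training_table <- function(n = 400, seed = 2) {
  withr::with_seed(seed, {
    depth <- stats::runif(n, 50, 2000)
    tab <- data.frame(
      bathymetry = -depth,
      slope = stats::runif(n, 0, 10),
      temperature = 13.1 + 5 * exp(-depth / 150) + stats::rnorm(n, 0, 0.4),
      salinity = stats::rnorm(n, 38.6, 0.35),
      current_velocity = stats::rlnorm(n, log(0.012), 0.6))
    lg <- -3 + 4 * exp(-(depth - 650)^2 / (2 * 200^2)) -
      1.5 * pmax(0, tab$temperature - 14)
    tab <- cbind(detected = stats::rbinom(n, 1, stats::plogis(lg)), tab)
    attr(tab, "predictors") <- setdiff(names(tab), "detected")
    tab
  })
}

# layer values at row-major cell ids (mirror of the package-internal lookup)
layer_at_cells_test <- function(layer, cells) {
  as.vector(t(layer$values))[cells]
}

# brute-force AUC over all presence/absence pairs (ties count one half)
auc_bruteforce <- function(obs, pred) {
  p1 <- pred[obs == 1]; p0 <- pred[obs == 0]
  s <- 0
  for (a in p1) for (b in p0)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(p1) * length(p0))
}

# dense-grid scan oracle for the TSS-optimal threshold
best_tss_gridscan <- function(obs, pred, step = 0.001) {
  grid <- seq(0, 1, by = step)
  max(vapply(grid, function(t) {
    cm <- confusion_metrics(obs, pred, t)
    cm$tss
  }, numeric(1)))
}
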