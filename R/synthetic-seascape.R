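#' Parameters of the synthetic suitability truth
#'
#' The synthetic seascape carries a known occurrence-probability surface
#' ("truth") built on the logit scale from unimodal responses to depth,
#' salinity and current velocity, a monotone decline above a temperature
#' onset, and a weak positive slope effect:
#'
#' \deqn{logit(p) = b_0 + a_d e^{-(d - d_{opt})^2 / 2\sigma_d^2}
#'   + a_s e^{-(S - S_{opt})^2 / 2\sigma_s^2}
#'   + a_c e^{-(v - v_{opt})^2 / 2\sigma_c^2}
#'   - \beta_T \max(0, T - T_{max}) + \beta_{slope} \cdot slope}
#'
#' Defaults describe a bathyal mud species: depth optimum 650 m, salinity
#' optimum 38.8 psu, current optimum 0.01 m/s, suitability declining above
#' 14 degC, and a 1.5 degC warming in the future scenario.
#'
#' @param depth_opt,depth_sd depth optimum and bump width (m).
#' @param temp_max temperature (degC) above which suitability declines.
#' @param temp_decline logit decline per degC above `temp_max`.
#' @param sal_opt,sal_sd salinity optimum and width (psu).
#' @param curr_opt,curr_sd current-velocity optimum and width (m/s).
#' @param slope_effect logit units per degree of slope.
#' @param intercept baseline logit.
#' @param depth_amp,sal_amp,curr_amp bump amplitudes (logit units).
#' @param warming degC added to the temperature layer in the future
#'   scenario (>= 0).
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(depth_opt = 650, depth_sd = 175,
                         temp_max = 14, temp_decline = 2,
                         sal_opt = 38.8, sal_sd = 0.4,
                         curr_opt = 0.01, curr_sd = 0.008,
                         slope_effect = 0.08, intercept = -5.5,
                         depth_amp = 5, sal_amp = 2, curr_amp = 1.5,
                         warming = 1.5) {
  stopifnot(depth_sd > 0, sal_sd > 0, curr_sd > 0, warming >= 0)
  structure(as.list(environment()), class = "truth_params")
}

#' Survey design for synthetic occurrence sampling
#'
#' Emulates the data situation of a basin-wide trawl survey (presence AND
#' absence stations) complemented by presence-only zones (ROV and
#' literature records) which will later require pseudo-absences.
#'
#' @param n_survey_stations number of survey stations (uniform over cells
#'   shallower than 2000 m, outside the presence-only zones).
#' @param presence_only_regions list of lon/lat boxes, each
#'   `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param n_presence_only total presence-only records, sampled inside the
#'   boxes proportionally to the truth.
#' @param seed integer seed for the sampling stream.
#' @return Object of class `survey_design`.
#' @export
survey_design <- function(n_survey_stations = 2500,
                          presence_only_regions = list(),
                          n_presence_only = 100,
                          seed = 1L) {
  stopifnot(n_survey_stations >= 0, n_presence_only >= 0)
  structure(list(n_survey_stations = as.integer(n_survey_stations),
                 presence_only_regions = presence_only_regions,
                 n_presence_only = as.integer(n_presence_only),
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Default presence-only zones for a grid
#'
#' Two boxes in the depth band that holds the suitability optimum, at
#' opposite ends of the basin, mimicking regionally clustered ROV surveys.
#'
#' @param grid a [grid_spec()].
#' @return list of two `c(lon_min, lon_max, lat_min, lat_max)` boxes.
#' @export
default_presence_only_regions <- function(grid) {
  W <- grid$n_cols * grid$cell_size
  H <- grid$n_rows * grid$cell_size
  box <- function(fx1, fx2, fy1, fy2)
    c(grid$lon_min + fx1 * W, grid$lon_min + fx2 * W,
      grid$lat_min + fy1 * H, grid$lat_min + fy2 * H)
  list(box(0.05, 0.25, 0.55, 0.75), box(0.70, 0.90, 0.55, 0.75))
}

# run code with a private RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic derived seed for a named sub-stream, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Gaussian smoothing of a matrix
#'
#' Separable truncated-Gaussian convolution with edge renormalisation
#' (kernel weights are rescaled to sum to one where the window is cut by
#' the border, so constants are preserved). Used to turn white noise into
#' spatially autocorrelated fields; the kernel width in cells sets the
#' autocorrelation range, which is what makes spatial blocking matter.
#'
#' @param m numeric matrix (no NA).
#' @param sigma kernel standard deviation in cells.
#' @return smoothed matrix of the same dimension.
#' @export
gaussian_smooth <- function(m, sigma) {
  stopifnot(sigma > 0, !anyNA(m))
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - h):min(n, i + h)
      w <- k[j - i + h + 1L]
      B[i, j] <- w / sum(w)
    }
    B
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# standardized smooth random field (mean 0, sd 1)
random_field <- function(n_rows, n_cols, sigma) {
  f <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Evaluate the truth suitability on a predictor stack
#'
#' @param stack a [predictor_stack()] with layers `bathymetry`, `slope`,
#'   `temperature`, `salinity`, `current_velocity`.
#' @param params a [truth_params()].
#' @return [raster_layer()] of occurrence probability in \[0, 1\].
#' @export
truth_suitability <- function(stack, params) {
  ly <- stack$layers
  need <- c("bathymetry", "slope", "temperature", "salinity",
            "current_velocity")
  if (!all(need %in% names(ly)))
    stop("stack lacks layers: ",
         paste(setdiff(need, names(ly)), collapse = ", "))
  d <- -ly$bathymetry$values           # positive depth in metres
  p <- params
  logit <- p$intercept +
    p$depth_amp * exp(-(d - p$depth_opt)^2 / (2 * p$depth_sd^2)) +
    p$sal_amp * exp(-(ly$salinity$values - p$sal_opt)^2 / (2 * p$sal_sd^2)) +
    p$curr_amp * exp(-(ly$current_velocity$values - p$curr_opt)^2 /
                       (2 * p$curr_sd^2)) -
    p$temp_decline * pmax(0, ly$temperature$values - p$temp_max) +
    p$slope_effect * ly$slope$values
  raster_layer(stack$grid, stats::plogis(logit), "truth", "probability")
}

#' Generate a synthetic seascape
#'
#' Builds a complete, internally consistent study system on one grid:
#' a shelf-to-basin bathymetry (0 to about -2600 m) with correlated
#' roughness; slope derived from it by [horn_slope()]; near-bottom
#' temperature warm on the shelf and near-isothermal at depth with an
#' independent lateral gradient (eastern basin warmer); salinity around
#' 38-39 psu increasing eastward; a log-normal smooth current-velocity
#' field; the truth suitability of [truth_suitability()]; a future stack
#' identical to the present except temperature + `warming`; a patchy
#' fishing-effort field concentrated on the 200-800 m belt; and three
#' contiguous region labels (west / central / east).
#'
#' Borders of the slope layer (and hence of the truth) are nodata, which
#' exercises nodata propagation downstream.
#'
#' @param grid a [grid_spec()], at least 50 x 50.
#' @param params a [truth_params()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements `present`, `future` ([predictor_stack()]s),
#'   `truth`, `truth_future`, `fishing`, `regions` ([raster_layer()]s).
#' @export
generate_seascape <- function(grid, params = truth_params(), seed = 1L) {
  if (grid$n_rows < 50 || grid$n_cols < 50)
    stop("grid must be at least 50x50 for meaningful spatial structure")
  nr <- grid$n_rows; nc <- grid$n_cols
  with_seed(derive_seed(seed, 1L), {
    fr <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)        # 0 north -> 1 south
    fc <- matrix((seq_len(nc) - 0.5) / nc, nr, nc, byrow = TRUE)
    elev <- -2500 * fr^1.3 + 220 * random_field(nr, nc, 4)
    elev <- pmin(elev, -5)
    bathy <- raster_layer(grid, elev, "bathymetry", "m")
    slope <- horn_slope(bathy)
    d <- -elev
    temp <- 13.1 + 5 * exp(-d / 150) + 0.8 * random_field(nr, nc, 6) +
      0.6 * fc
    sal <- 38.4 + 0.35 * random_field(nr, nc, 6) + 0.3 * fc
    curr <- exp(log(0.012) + 0.6 * random_field(nr, nc, 5))
    mk <- function(v, nm, un) raster_layer(grid, v, nm, un)
    present <- predictor_stack(list(
      bathymetry = bathy, slope = slope,
      temperature = mk(temp, "temperature", "degC"),
      salinity = mk(sal, "salinity", "psu"),
      current_velocity = mk(curr, "current_velocity", "m/s")),
      scenario = "present")
    future <- present
    future$scenario <- "rcp85"
    future$layers$temperature <- mk(temp + params$warming,
                                    "temperature", "degC")
    truth <- truth_suitability(present, params)
    truth_future <- truth_suitability(future, params)
    # patchy effort on trawlable depths, zero outside the patches
    base <- 12 * exp(1.2 * random_field(nr, nc, 3)) *
      exp(-((d - 500) / 350)^2)
    cut <- stats::quantile(base, 0.35)
    base[base <= cut] <- 0
    fishing <- mk(base, "fishing_effort", "h/km2/yr")
    reg <- matrix(1L, nr, nc)
    reg[fc > 1 / 3] <- 2L
    reg[fc > 2 / 3] <- 3L
    regions <- mk(reg + 0, "regions", "label")
    list(present = present, future = future, truth = truth,
         truth_future = truth_future, fishing = fishing, regions = regions)
  })
}

#' Sample synthetic occurrence records
#'
#' Survey stations are placed uniformly (without replacement) over valid
#' truth cells shallower than 2000 m and outside the presence-only boxes;
#' each station detects the species with probability equal to the truth at
#' its cell. Presence-only records are sampled inside the boxes with
#' probability proportional to the truth and are all detections.
#'
#' @param truth [raster_layer()] of occurrence probability.
#' @param bathymetry [raster_layer()] on the same grid (m, negative down).
#' @param design a [survey_design()].
#' @return data.frame with columns `lon`, `lat`, `detected`, `source`,
#'   `year`.
#' @export
sample_occurrences <- function(truth, bathymetry, design) {
  stop_if_grid_mismatch(truth, bathymetry)
  g <- truth$grid
  tv <- as.vector(t(truth$values))
  if (all(is.na(tv))) stop("truth layer is entirely nodata")
  if (any(tv < 0 | tv > 1, na.rm = TRUE)) stop("truth must lie in [0, 1]")
  dv <- -as.vector(t(bathymetry$values))
  lon <- rep(cell_lons(g), times = g$n_rows)
  lat <- rep(cell_lats(g), each = g$n_cols)
  in_box <- rep(FALSE, length(tv))
  for (b in design$presence_only_regions) {
    if (b[1] < g$lon_min || b[3] < g$lat_min ||
        b[2] > g$lon_min + g$n_cols * g$cell_size ||
        b[4] > g$lat_min + g$n_rows * g$cell_size)
      stop("presence-only box outside grid extent")
    in_box <- in_box | (lon >= b[1] & lon <= b[2] & lat >= b[3] & lat <= b[4])
  }
  with_seed(derive_seed(design$seed, 2L), {
    elig <- which(!is.na(tv) & !is.na(dv) & dv < 2000 & !in_box)
    if (length(elig) < design$n_survey_stations)
      stop("not enough eligible cells for the requested survey size")
    st <- sample(elig, design$n_survey_stations)
    survey <- data.frame(
      lon = lon[st], lat = lat[st],
      detected = stats::rbinom(length(st), 1L, tv[st]),
      source = "survey",
      year = sample(2000:2020, length(st), replace = TRUE))
    po <- NULL
    if (design$n_presence_only > 0) {
      pool <- which(in_box & !is.na(tv))
      if (length(pool) == 0) stop("presence-only boxes cover no valid cells")
      pick <- sample(pool, design$n_presence_only,
                     replace = length(pool) < design$n_presence_only,
                     prob = tv[pool])
      po <- data.frame(lon = lon[pick], lat = lat[pick], detected = 1L,
                       source = "presence_only",
                       year = sample(2000:2020, length(pick), replace = TRUE))
    }
    rbind(survey, po)
  })
}
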