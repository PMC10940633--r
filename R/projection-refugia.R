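#' Binarise an ensemble suitability map
#'
#' @param suitability [raster_layer()] with values in \[0, 1\].
#' @param threshold classification threshold in \[0, 1\]; a cell is
#'   suitable iff its value is `>= threshold`.
#' @return binary [raster_layer()] (0/1, nodata propagated).
#' @export
binarize_ensemble <- function(suitability, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  v <- suitability$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  binarize_layer(suitability, threshold)
}

#' Classify habitat change between present and future
#'
#' Cross-tabulates the two binary suitability maps into the four change
#' classes: gain (unsuitable now, suitable in the future), loss (suitable
#' now, not in the future), refugia (suitable in both periods) and
#' absence (suitable in neither). Class areas are accumulated with
#' [cell_area()].
#'
#' @param present_binary,future_binary binary [raster_layer()]s on one
#'   grid.
#' @return object of class `change_map`: list with `map` (categorical
#'   [raster_layer()], codes in attribute `"classes"`), `areas_km2` and
#'   `cells` (named per-class totals).
#' @export
classify_change <- function(present_binary, future_binary) {
  stop_if_grid_mismatch(present_binary, future_binary)
  p <- present_binary$values; f <- future_binary$values
  if (!all(p %in% c(0, 1) | is.na(p)) || !all(f %in% c(0, 1) | is.na(f)))
    stop("inputs must be binary 0/1 maps")
  codes <- c(gain = 1, loss = 2, refugia = 3, absence = 4)
  m <- matrix(NA_real_, nrow(p), ncol(p))
  m[p == 0 & f == 1] <- codes["gain"]
  m[p == 1 & f == 0] <- codes["loss"]
  m[p == 1 & f == 1] <- codes["refugia"]
  m[p == 0 & f == 0] <- codes["absence"]
  map <- raster_layer(present_binary$grid, m, "habitat_change", "class")
  attr(map, "classes") <- codes
  area <- cell_area(present_binary$grid)$values
  areas <- vapply(codes, function(cd) sum(area[!is.na(m) & m == cd]), 0)
  cells <- vapply(codes, function(cd) sum(!is.na(m) & m == cd), 0)
  structure(list(map = map, areas_km2 = areas, cells = cells),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat("<change_map> areas (km2):\n")
  print(round(x$areas_km2, 1))
  invisible(x)
}

#' Habitat loss, gain and refugia relative to the present range
#'
#' Percentages are taken over the currently suitable area (loss +
#' refugia): `loss_pct` is the share of today's suitable habitat no
#' longer suitable in the future, `gain_pct` the newly suitable area in
#' the same units. Both area-weighted (primary) and raw cell-count
#' versions are reported.
#'
#' @param change a [classify_change()] result.
#' @return list: `loss_pct`, `gain_pct`, `refugia_pct`, cell-count
#'   variants (`*_pct_cells`), and the per-class `areas_km2`.
#' @export
habitat_change_summary <- function(change) {
  a <- change$areas_km2
  present_suitable <- a["loss"] + a["refugia"]
  if (present_suitable == 0) stop("no present-suitable area")
  cc <- change$cells
  pc <- cc["loss"] + cc["refugia"]
  list(loss_pct = unname(100 * a["loss"] / present_suitable),
       gain_pct = unname(100 * a["gain"] / present_suitable),
       refugia_pct = unname(100 * a["refugia"] / present_suitable),
       loss_pct_cells = unname(100 * cc["loss"] / pc),
       gain_pct_cells = unname(100 * cc["gain"] / pc),
       areas_km2 = a)
}

#' Restrict a layer to the study area
#'
#' The analysis is confined to cells shallower than `max_depth_m`;
#' deeper cells (and land) become nodata before any classification.
#'
#' @param layer [raster_layer()] to mask.
#' @param bathymetry [raster_layer()] in metres (negative below sea
#'   level) on the same grid.
#' @param max_depth_m depth cut-off (default 2000).
#' @return the masked [raster_layer()].
#' @export
mask_study_area <- function(layer, bathymetry, max_depth_m = 2000) {
  stop_if_grid_mismatch(layer, bathymetry)
  v <- layer$values
  d <- -bathymetry$values
  v[is.na(d) | d > max_depth_m | d < 0] <- NA_real_
  out <- layer
  out$values <- v
  out
}
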