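#' Grid specification for a geographic raster
#'
#' A `grid_spec` describes a regular lon/lat grid with cell-centre
#' registration. `lon_min` and `lat_min` are the *outer edges* of the
#' south-western cell; cell centres are offset by half a cell. Row 1 is the
#' northernmost row, matching the usual top-down raster storage order. All
#' coordinates are decimal degrees on a geographic (EPSG:4326-style) grid.
#'
#' @param lon_min,lat_min western and southern edge of the grid (degrees).
#' @param cell_size cell side in decimal degrees (> 0); cells are square.
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(5, 31, 0.25, 60, 60)
#' head(cell_lons(g))
#' @export
grid_spec <- function(lon_min, lat_min, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1,
            n_rows == round(n_rows), n_cols == round(n_cols))
  structure(
    list(lon_min = as.numeric(lon_min), lat_min = as.numeric(lat_min),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols @ %g deg, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$lon_min, x$lat_min))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return `cell_lons()`: centre longitudes by column; `cell_lats()`:
#'   centre latitudes by row (row 1 = northernmost).
#' @export
cell_lons <- function(grid) {
  grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname cell_lons
#' @export
cell_lats <- function(grid) {
  grid$lat_min + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
}

#' Locate points on a grid
#'
#' Maps lon/lat points to (row, col) indices; points outside the grid edges
#' get NA. Points exactly on an interior edge belong to the cell to the
#' east / south of the edge, the conventional half-open tiling.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors of equal length.
#' @return data.frame with columns `row`, `col`, `cell` (cell =
#'   (row - 1) * n_cols + col, NA outside the grid).
#' @export
locate_cells <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  col <- floor((lon - grid$lon_min) / grid$cell_size) + 1L
  # latitude measured downward from the northern edge
  lat_max <- grid$lat_min + grid$n_rows * grid$cell_size
  row <- floor((lat_max - lat) / grid$cell_size) + 1L
  # points exactly on the northern/western outer edge fall in the first cell
  row[lat == lat_max] <- 1L
  col[lon == grid$lon_min] <- 1L
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols |
    is.na(lon) | is.na(lat)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = (as.integer(row) - 1L) * grid$n_cols + as.integer(col))
}

#' A single gridded variable
#'
#' Couples a value matrix (n_rows x n_cols, row 1 north) with its
#' [grid_spec()]. `NA` encodes nodata; all non-NA values must be finite.
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix of dim (n_rows, n_cols).
#' @param name,units layer label and units (free text).
#' @return Object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values matrix does not match grid dimensions")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values present; use NA for nodata")
  structure(list(grid = grid, values = values,
                 name = as.character(name), units = as.character(units)),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> '%s' [%s] %dx%d, %d valid cells, range [%g, %g]\n",
              x$name, x$units, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$lon_min - b$lon_min) < tol && abs(a$lat_min - b$lat_min) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  ga <- if (inherits(a, "raster_layer")) a$grid else a
  gb <- if (inherits(b, "raster_layer")) b$grid else b
  if (!same_grid(ga, gb)) stop(what, " are not on the same grid")
  invisible(TRUE)
}

#' Resample a layer onto a target grid
#'
#' Homogenises layers of different native resolutions onto the working
#' grid: finer-scale layers are downscaled by averaging all source cell
#' centres falling into each target cell (nodata ignored); coarser layers
#' are upscaled by bilinear interpolation from the four surrounding source
#' cell centres. Target cells with no contributing data are nodata, as is
#' any bilinear target touching a nodata source centre.
#'
#' @param layer a [raster_layer()].
#' @param target a [grid_spec()] for the output.
#' @param direction `"mean_downscale"` (target coarser or equal) or
#'   `"bilinear_upscale"` (target finer or equal).
#' @return A [raster_layer()] on `target`.
#' @export
resample_layer <- function(layer, target,
                           direction = c("mean_downscale", "bilinear_upscale")) {
  direction <- match.arg(direction)
  src <- layer$grid
  if (same_grid(src, target)) return(raster_layer(target, layer$values,
                                                  layer$name, layer$units))
  tol <- 1e-9
  if (direction == "mean_downscale" && target$cell_size < src$cell_size - tol)
    stop("mean_downscale requires target cell_size >= source cell_size")
  if (direction == "bilinear_upscale" && target$cell_size > src$cell_size + tol)
    stop("bilinear_upscale requires target cell_size <= source cell_size")

  if (direction == "mean_downscale") {
    lon <- rep(cell_lons(src), each = src$n_rows)
    lat <- rep(cell_lats(src), times = src$n_cols)
    loc <- locate_cells(target, lon, lat)
    v <- as.vector(layer$values)
    keep <- !is.na(loc$cell)
    if (!any(keep)) stop("no overlap between source and target grids")
    keep2 <- keep & !is.na(v)
    out <- rep(NA_real_, target$n_rows * target$n_cols)
    if (any(keep2)) {
      sums <- tapply(v[keep2], loc$cell[keep2], mean)
      out[as.integer(names(sums))] <- as.numeric(sums)
    }
    vals <- matrix(out, target$n_rows, target$n_cols, byrow = TRUE)
    return(raster_layer(target, vals, layer$name, layer$units))
  }

  # bilinear from source cell centres
  tl <- cell_lons(target); tla <- cell_lats(target)
  sl <- cell_lons(src);    sla <- cell_lats(src)
  # fractional column position of each target centre among source centres
  fx <- (rep(tl, each = target$n_rows) - sl[1]) / src$cell_size
  # source latitudes decrease with row; position measured from row 1 down
  fy <- (sla[1] - rep(tla, times = target$n_cols)) / src$cell_size
  inside <- fx >= -tol & fx <= src$n_cols - 1 + tol &
    fy >= -tol & fy <= src$n_rows - 1 + tol
  if (!any(inside)) stop("no overlap between source and target grids")
  j0 <- pmin(pmax(floor(fx), 0), src$n_cols - 2L)
  i0 <- pmin(pmax(floor(fy), 0), src$n_rows - 2L)
  if (src$n_cols == 1L) j0 <- rep(0L, length(fx))
  if (src$n_rows == 1L) i0 <- rep(0L, length(fy))
  wx <- pmin(pmax(fx - j0, 0), 1); wy <- pmin(pmax(fy - i0, 0), 1)
  z <- layer$values
  pick <- function(di, dj) z[cbind(i0 + 1L + di, j0 + 1L + dj)]
  v00 <- pick(0L, 0L); v01 <- pick(0L, min(1L, src$n_cols - 1L))
  v10 <- pick(min(1L, src$n_rows - 1L), 0L)
  v11 <- pick(min(1L, src$n_rows - 1L), min(1L, src$n_cols - 1L))
  out <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
    wy * ((1 - wx) * v10 + wx * v11)
  out[!inside] <- NA_real_
  vals <- matrix(out, target$n_rows, target$n_cols)
  raster_layer(target, vals, layer$name, layer$units)
}

# Earth radius used for all degree->metre conversions (metres)
.earth_radius_m <- 6371000
.km_per_degree <- 111.19

#' Terrain slope by Horn's eight-neighbour method
#'
#' Computes slope in degrees from a bathymetry/elevation layer using
#' Horn's 1-2-1 weighted finite differences over the eight neighbours.
#' Horizontal spacing is converted from degrees to metres with a fixed
#' Earth radius; the east-west spacing shrinks with cos(latitude) row by
#' row. Border cells and cells with any nodata neighbour are nodata.
#'
#' @param bathymetry a [raster_layer()] of elevation in metres (negative
#'   below sea level) on a degree grid.
#' @return A [raster_layer()] of slope in degrees, in \[0, 90).
#' @export
horn_slope <- function(bathymetry) {
  g <- bathymetry$grid
  if (g$n_rows < 3 || g$n_cols < 3) stop("raster must be at least 3x3")
  z <- bathymetry$values
  nr <- g$n_rows; nc <- g$n_cols
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  sh <- function(di, dj) z[ri + di, ci + dj, drop = FALSE]
  dy_m <- g$cell_size * (pi / 180) * .earth_radius_m
  dx_m <- g$cell_size * (pi / 180) * .earth_radius_m *
    cos(cell_lats(g)[ri] * pi / 180)
  dzdx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * dx_m)
  # row 1 is north: decreasing row index means increasing latitude
  dzdy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
           (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (8 * dy_m)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # the centre cell is not consumed by the 1-2-1 differences, but a slope
  # at a nodata cell would be meaningless: propagate explicitly
  slope[is.na(sh(0, 0))] <- NA_real_
  out <- matrix(NA_real_, nr, nc)
  out[ri, ci] <- slope
  raster_layer(g, out, name = "slope", units = "degrees")
}

#' Per-cell area of a geographic grid
#'
#' Exact spherical cell areas in km^2: `A = R^2 * dlambda * (sin(phi_top) -
#' sin(phi_bottom))` with R = 6371 km. Constant along a row, shrinking
#' toward the poles.
#'
#' @param grid a [grid_spec()].
#' @return A [raster_layer()] of areas (km^2), no nodata.
#' @export
cell_area <- function(grid) {
  R <- 6371
  cs <- grid$cell_size * pi / 180
  lat_top <- (cell_lats(grid) + grid$cell_size / 2) * pi / 180
  lat_bot <- (cell_lats(grid) - grid$cell_size / 2) * pi / 180
  row_area <- R^2 * cs * (sin(lat_top) - sin(lat_bot))
  raster_layer(grid, matrix(row_area, grid$n_rows, grid$n_cols),
               name = "cell_area", units = "km2")
}

#' Read and write rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster interchange: the six-line header carries
#' the full grid specification (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value) followed by rows north to south. Values are written at
#' full double precision so a write/read round trip is exact. Only
#' cell-centre-registered square-cell geographic grids are supported;
#' `xllcenter`-registered files are rejected.
#'
#' @param path file path (conventionally `.asc`).
#' @param layer a [raster_layer()] (for writing).
#' @param name,units metadata for the layer read (the format itself stores
#'   neither); `name` defaults to the file stem.
#' @param nodata sentinel written for NA cells.
#' @return `read_raster()`: a [raster_layer()]. `write_raster()`: the path,
#'   invisibly.
#' @export
read_raster <- function(path, name = NULL, units = "") {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("not a corner-registered single-band ASCII grid: ", path)
  g <- grid_spec(vals["xllcorner"], vals["yllcorner"], vals["cellsize"],
                 vals["nrows"], vals["ncols"])
  dat <- scan(path, skip = 6L, quiet = TRUE)
  if (length(dat) != g$n_rows * g$n_cols)
    stop("cell count does not match header (multi-band data?): ", path)
  m <- matrix(dat, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(g, m, name = name, units = units)
}

#' @rdname read_raster
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  v <- layer$values
  if (any(v[!is.na(v)] == nodata))
    stop("a data value equals the nodata sentinel ", nodata)
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.17g", g$lon_min),
           sprintf("yllcorner %.17g", g$lat_min),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("NODATA_value %.17g", nodata))
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bundle named layers on one grid
#'
#' A predictor stack holds the environmental layers used for model fitting
#' and prediction, all on one shared grid, tagged with the scenario they
#' describe (`"present"` or `"rcp85"`). The future stack differs from the
#' present one only in the climate variables (temperature, salinity,
#' current velocity); the terrain layers are shared.
#'
#' @param layers named list of [raster_layer()]s on a common grid.
#' @param scenario `"present"` or `"rcp85"`.
#' @return Object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, scenario = c("present", "rcp85")) {
  scenario <- match.arg(scenario)
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            !anyDuplicated(names(layers)))
  g <- layers[[1]]$grid
  for (ly in layers) stop_if_grid_mismatch(g, ly, "stack layers")
  structure(list(layers = layers, grid = g, scenario = scenario),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> scenario=%s, %d layers: %s (%dx%d)\n",
              x$scenario, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Stack values as a per-cell data frame
#'
#' @param stack a [predictor_stack()].
#' @return data.frame with one row per grid cell (in cell order: row-major,
#'   row 1 first) and one column per layer, plus a `cell` index column.
#' @export
stack_table <- function(stack) {
  out <- lapply(stack$layers, function(ly) as.vector(t(ly$values)))
  df <- as.data.frame(out)
  df$cell <- seq_len(stack$grid$n_rows * stack$grid$n_cols)
  df
}

# values of a layer at cell ids (row-major order, row 1 first)
layer_at_cells <- function(layer, cells) {
  as.vector(t(layer$values))[cells]
}

# replace values at cell ids
set_cells <- function(layer, cells, values) {
  v <- t(layer$values)
  v[cells] <- values
  layer$values <- t(v)
  layer
}
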