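#' Implant pseudo-absences in presence-only zones
#'
#' Survey programmes provide true absences, but ROV and literature records
#' are presence-only; modelling them together would bias the intercept.
#' For each presence-only region the function implants pseudo-absence
#' records at uniformly random unoccupied cell centres within the region,
#' in number `round(n_presences_in_region * (survey absences / survey
#' presences))`, so the regional prevalence matches the survey's. Cells
#' deeper than 1000 m are never used (trawling, and hence the survey's
#' absence information, stops there), nor are cells already holding any
#' record.
#'
#' @param records occurrence data.frame (`lon`, `lat`, `detected`,
#'   `source`, ...).
#' @param presence_only_regions list of `c(lon_min, lon_max, lat_min,
#'   lat_max)` boxes.
#' @param bathymetry [raster_layer()] in metres (negative below sea level).
#' @param seed integer seed.
#' @return the records with pseudo-absence rows appended
#'   (`source = "pseudo_absence"`, `detected = 0`).
#' @export
add_pseudo_absences <- function(records, presence_only_regions, bathymetry,
                                seed = 1L) {
  if (length(presence_only_regions) == 0) return(records)
  sv <- records$source == "survey"
  n_pres <- sum(sv & records$detected == 1)
  n_abs <- sum(sv & records$detected == 0)
  if (n_pres == 0) stop("no survey presences: presence/absence ratio undefined")
  if (n_abs == 0) stop("no survey absences: presence/absence ratio undefined")
  ratio <- n_abs / n_pres
  g <- bathymetry$grid
  lon_c <- rep(cell_lons(g), times = g$n_rows)
  lat_c <- rep(cell_lats(g), each = g$n_cols)
  depth <- -as.vector(t(bathymetry$values))
  occupied <- rep(FALSE, length(depth))
  loc <- locate_cells(g, records$lon, records$lat)
  occupied[loc$cell[!is.na(loc$cell)]] <- TRUE
  out <- records
  with_seed(derive_seed(seed, 3L), {
    for (b in presence_only_regions) {
      in_b <- records$lon >= b[1] & records$lon <= b[2] &
        records$lat >= b[3] & records$lat <= b[4]
      n_pa <- round(sum(in_b & records$detected == 1) * ratio)
      if (n_pa == 0) next
      elig <- which(lon_c >= b[1] & lon_c <= b[2] &
                      lat_c >= b[3] & lat_c <= b[4] &
                      !is.na(depth) & depth <= 1000 & !occupied)
      if (length(elig) == 0) {
        warning("presence-only region has no eligible cells; none added")
        next
      }
      if (length(elig) < n_pa) {
        warning(sprintf(
          "region has only %d eligible cells for %d pseudo-absences",
          length(elig), n_pa))
        n_pa <- length(elig)
      }
      pick <- if (length(elig) == 1L) elig else sample(elig, n_pa)
      occupied[pick] <- TRUE
      add <- records[rep(NA_integer_, length(pick)), , drop = FALSE]
      add$lon <- lon_c[pick]; add$lat <- lat_c[pick]
      add$detected <- 0L; add$source <- "pseudo_absence"
      rownames(add) <- NULL
      out <- rbind(out, add)
    }
  })
  rownames(out) <- NULL
  out
}

#' Aggregate occurrence records to one per grid cell
#'
#' Repeated trawls and multi-year detections of the same colonies inflate
#' spatial autocorrelation; the model-ready dataset keeps a single record
#' per working-grid cell. If a cell holds at least one presence, one of
#' its presences is kept (chosen uniformly at random); otherwise one of
#' its absences. A single detection is taken as sufficient evidence that
#' the cell's conditions are suitable, so co-located "noisy absences" are
#' dropped.
#'
#' @param records occurrence data.frame; all records must fall inside the
#'   grid.
#' @param grid the working [grid_spec()].
#' @param seed integer seed for the random within-cell choice.
#' @return data.frame with columns `cell`, `lon`, `lat`, `detected`,
#'   `source` (plus any other columns of the input), one row per occupied
#'   cell, carrying the grid as attribute `"grid"`.
#' @export
aggregate_to_grid <- function(records, grid, seed = 1L) {
  if (is.null(records) || nrow(records) == 0) stop("no records to aggregate")
  loc <- locate_cells(grid, records$lon, records$lat)
  if (anyNA(loc$cell)) stop("records fall outside the grid extent")
  with_seed(derive_seed(seed, 4L), {
    ord <- sample.int(nrow(records))       # random tie-break within cells
    r <- records[ord, , drop = FALSE]
    cl <- loc$cell[ord]
    # presences first, then random order: the first row per cell is a
    # uniformly random presence if the cell has one, else a random absence
    o2 <- order(cl, -r$detected)
    r <- r[o2, , drop = FALSE]; cl <- cl[o2]
    keep <- !duplicated(cl)
    out <- cbind(cell = cl[keep], r[keep, , drop = FALSE])
    rownames(out) <- NULL
    attr(out, "grid") <- grid
    out
  })
}

#' Attach predictor values to aggregated records
#'
#' Looks up every stack layer at each record's grid cell. Records landing
#' on any nodata predictor cell are dropped; the number dropped is
#' reported via a message and the `"n_dropped"` attribute.
#'
#' @param dataset output of [aggregate_to_grid()] (must be on the stack's
#'   grid).
#' @param stack a [predictor_stack()].
#' @return the dataset with one numeric column per layer appended.
#' @export
extract_predictors <- function(dataset, stack) {
  g <- attr(dataset, "grid")
  if (is.null(g)) stop("dataset lacks a grid attribute; aggregate it first")
  stop_if_grid_mismatch(g, stack$grid, "dataset and stack")
  vals <- lapply(stack$layers, layer_at_cells, cells = dataset$cell)
  out <- cbind(dataset, as.data.frame(vals))
  ok <- stats::complete.cases(out[names(stack$layers)])
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " record(s) on nodata predictor cells dropped")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- g
  attr(out, "predictors") <- names(stack$layers)
  attr(out, "n_dropped") <- n_dropped
  out
}
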