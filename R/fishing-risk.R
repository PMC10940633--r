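#' Quartile fishing-risk classes
#'
#' Discretises a fishing-effort raster (hours per km2 per year) into four
#' risk levels at the quartiles of the positive-effort cells, with
#' zero-effort cells kept as their own class: low (0, Q1], medium
#' (Q1, Q2], high (Q2, Q3], very high (> Q3). Quartiles use the standard
#' linear-interpolation convention (`stats::quantile` type 7) and are
#' always recomputed from the data.
#'
#' @param fishing effort [raster_layer()], values >= 0.
#' @param n_min minimum number of positive-effort cells required.
#' @return object of class `risk_map`: list with `map` (categorical
#'   [raster_layer()], codes 0 no_effort, 1 low, 2 medium, 3 high,
#'   4 very_high in attribute `"classes"`) and `edges` (Q1, Q2, Q3 in
#'   hours).
#' @export
risk_levels <- function(fishing, n_min = 4) {
  v <- fishing$values
  if (any(v < 0, na.rm = TRUE)) stop("fishing effort must be non-negative")
  pos <- v[!is.na(v) & v > 0]
  if (length(pos) < n_min)
    stop("need at least ", n_min, " cells with positive effort")
  q <- stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[v == 0] <- 0
  cls[v > 0 & v <= q[1]] <- 1
  cls[v > q[1] & v <= q[2]] <- 2
  cls[v > q[2] & v <= q[3]] <- 3
  cls[v > q[3]] <- 4
  map <- raster_layer(fishing$grid, cls, "fishing_risk", "class")
  attr(map, "classes") <- c(no_effort = 0, low = 1, medium = 2, high = 3,
                            very_high = 4)
  structure(list(map = map, edges = q), class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  cat(sprintf("<risk_map> quartile edges: %.2f / %.2f / %.2f h\n",
              x$edges[1], x$edges[2], x$edges[3]))
  invisible(x)
}

#' Overlay risk classes on a habitat footprint by region
#'
#' Sums the spherical cell areas of target-positive cells by region and
#' risk class, plus a basin-wide `"all"` row per class, quantifying how
#' much observed, suitable or refugial habitat sits under each level of
#' trawling pressure.
#'
#' @param risk a [risk_levels()] result.
#' @param target binary 0/1 [raster_layer()] (observed-presence,
#'   present-suitable, or refugia footprint).
#' @param regions [raster_layer()] of integer region labels.
#' @return data.frame with columns `region`, `risk_class`, `area_km2`.
#' @export
overlay_risk <- function(risk, target, regions) {
  stop_if_grid_mismatch(risk$map, target)
  stop_if_grid_mismatch(risk$map, regions)
  cls <- risk$map$values
  tv <- target$values
  if (!all(tv %in% c(0, 1) | is.na(tv))) stop("target must be binary 0/1")
  area <- cell_area(target$grid)$values
  classes <- attr(risk$map, "classes")
  reg_labels <- sort(unique(regions$values[!is.na(regions$values)]))
  rows <- list()
  for (rg in c(as.list(reg_labels), list(NULL))) {
    in_reg <- if (is.null(rg)) !is.na(regions$values)
              else !is.na(regions$values) & regions$values == rg
    for (ci in seq_along(classes)) {
      sel <- in_reg & !is.na(tv) & tv == 1 & !is.na(cls) &
        cls == classes[ci]
      rows[[length(rows) + 1L]] <- data.frame(
        region = if (is.null(rg)) "all" else as.character(rg),
        risk_class = names(classes)[ci],
        area_km2 = sum(area[sel]))
    }
  }
  do.call(rbind, rows)
}
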