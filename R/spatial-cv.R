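#' Spatial blocks for cross-validation
#'
#' Occurrence data are spatially autocorrelated, so random record-level
#' folds leak information between train and test. A regular checkerboard
#' of square tiles (side `block_size_km`) is laid over the data extent and
#' every record labelled by its tile; folds are then assigned at the tile
#' level. The side is converted to degrees with 1 deg latitude =
#' 111.19 km and longitude scaled by cos of the records' mean latitude.
#'
#' @param dataset data.frame with `lon`, `lat` columns.
#' @param block_size_km tile side in kilometres (> 0); 250 km is the
#'   default working value for Mediterranean-scale data.
#' @return integer vector of block ids, one per record.
#' @export
build_blocks <- function(dataset, block_size_km = 250) {
  if (is.null(dataset) || nrow(dataset) == 0) stop("empty dataset")
  stopifnot(block_size_km > 0)
  mean_lat <- mean(dataset$lat)
  d_lat <- block_size_km / .km_per_degree
  d_lon <- block_size_km / (.km_per_degree * cos(mean_lat * pi / 180))
  tc <- floor((dataset$lon - min(dataset$lon)) / d_lon)
  tr <- floor((dataset$lat - min(dataset$lat)) / d_lat)
  as.integer(tr * (max(tc) + 1L) + tc + 1L)
}

#' Assign spatial blocks to folds
#'
#' Occupied blocks are shuffled and dealt round-robin to the folds, which
#' balances block counts and guarantees every fold is non-empty. All
#' records of a block share its fold, enforcing spatial independence
#' between train and test splits.
#'
#' @param blocks integer block id per record (from [build_blocks()]).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; different seeds give different assignments.
#' @return object of class `fold_assignment`: list with `fold` (integer
#'   per record), `block` (block id per record), `fold_of_block` (named
#'   map), `n_folds`.
#' @export
assign_folds <- function(blocks, n_folds = 5, seed = 1L) {
  occ <- sort(unique(blocks))
  if (length(occ) < n_folds)
    stop("fewer occupied blocks (", length(occ), ") than folds (",
         n_folds, ")")
  with_seed(derive_seed(seed, 5L), {
    shuffled <- sample(occ)
    fold_of_block <- ((seq_along(shuffled) - 1L) %% n_folds) + 1L
    names(fold_of_block) <- as.character(shuffled)
    structure(list(fold = unname(fold_of_block[as.character(blocks)]),
                   block = blocks,
                   fold_of_block = fold_of_block,
                   n_folds = as.integer(n_folds)),
              class = "fold_assignment")
  })
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d records, %d blocks, %d folds\n",
              length(x$fold), length(x$fold_of_block), x$n_folds))
  print(table(fold = x$fold))
  invisible(x)
}
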