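# Occurrence handling: CSV I/O, spatial thinning, regional split, predictor
# extraction.

#' Read / write occurrence records
#'
#' CSV with header `species,lon,lat`; coordinates are map units (the synthetic
#' landscape uses km on an arbitrary plane, so `lon`/`lat` are simply x/y).
#'
#' @param path CSV file path.
#' @param occ An `occurrence_set` data.frame (columns `species`, `x`, `y`).
#' @return `read_occurrences` returns an `occurrence_set`.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(d)))
    stop("occurrence CSV must have columns species,lon,lat")
  out <- data.frame(species = d$species, x = d$lon, y = d$lat)
  if ("region" %in% names(d)) out$region <- d$region
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  d <- data.frame(species = occ$species, lon = occ$x, lat = occ$y)
  if ("region" %in% names(occ)) d$region <- occ$region
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spatial thinning: one record per cell
#'
#' Buckets records into square thinning cells of edge `cell_size` anchored at
#' `origin` (half-open, as in [point_to_cell()]) and keeps the first record in
#' input order within each bucket. Deterministic and idempotent.
#'
#' @param occ An `occurrence_set`.
#' @param cell_size Thinning-cell edge in map units.
#' @param origin Anchor corner of the thinning lattice.
#' @return Thinned `occurrence_set` (same columns, original order).
#' @export
thin_occurrences <- function(occ, cell_size, origin = c(0, 0)) {
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  if (nrow(occ) == 0) return(occ)
  cx <- floor((occ$x - origin[1]) / cell_size)
  cy <- floor((occ$y - origin[2]) / cell_size)
  key <- paste(cx, cy)
  occ[!duplicated(key), , drop = FALSE]
}

#' Split occurrences into northern and southern regions
#'
#' Records with `y >= y_threshold` go north (a record exactly on the boundary
#' is assigned north); the rest south. Region labels are attached.
#'
#' @param occ An `occurrence_set`.
#' @param y_threshold Boundary y-coordinate.
#' @return List with elements `north` and `south`, both `occurrence_set`s.
#' @export
split_regions <- function(occ, y_threshold) {
  stopifnot(is.numeric(y_threshold), length(y_threshold) == 1L)
  is_n <- occ$y >= y_threshold
  north <- occ[is_n, , drop = FALSE]
  south <- occ[!is_n, , drop = FALSE]
  if (nrow(north)) north$region <- "north"
  if (nrow(south)) south$region <- "south"
  list(north = north, south = south)
}

#' Extract predictor values at occurrence points
#'
#' Maps each record to its containing grid cell and reads all layer values.
#' Records falling outside the grid or on masked cells are dropped; the drop
#' count is attached as attribute `dropped` (and a warning is emitted for
#' out-of-grid points).
#'
#' @param occ An `occurrence_set` or any data.frame with `x`, `y`.
#' @param stack An [env_stack()].
#' @return data.frame with columns `row`, `col` and one per layer;
#'   attribute `dropped` holds the dropped-record count.
#' @export
extract_predictors <- function(occ, stack) {
  cells <- point_to_cell(occ$x, occ$y, stack$grid)
  outside <- is.na(cells$row)
  if (any(outside))
    warning(sum(outside), " record(s) outside the grid dropped")
  masked <- rep(FALSE, nrow(cells))
  ok <- !outside
  masked[ok] <- stack$mask[cbind(cells$row[ok], cells$col[ok])]
  keep <- ok & !masked
  out <- stack_table(stack, cells[keep, , drop = FALSE])
  attr(out, "dropped") <- sum(!keep)
  out
}
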