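#' Grid geometry for a raster stack
#'
#' Defines the rectangular grid every layer of an [env_stack()] shares:
#' dimensions, cell size (km per side) and the map coordinates of the
#' lower-left corner. Cells are half-open squares `[x0 + (c-1)*cs, x0 + c*cs)`;
#' row 1 is the southernmost (lowest-y) row, so matrix element `[r, c]` covers
#' `y` in `[y0 + (r-1)*cs, y0 + r*cs)`.
#'
#' @param nrows,ncols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in km (map units), positive.
#' @param origin Numeric length-2, map coordinates `(x, y)` of the lower-left
#'   corner of cell `[1, 1]`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cell_size = 1, origin = c(0, 0)) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 1L || ncols < 1L)
    stop("grid dimensions must be positive integers")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number")
  if (!is.numeric(origin) || length(origin) != 2L)
    stop("origin must be a numeric vector of length 2")
  structure(list(nrows = nrows, ncols = ncols,
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %g km cells, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

same_grid <- function(a, b) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Map points to grid cells
#'
#' Half-open cell convention: a point on the shared edge between two cells
#' belongs to the cell with the larger index. Points outside the grid get NA.
#'
#' @param x,y Map coordinates.
#' @param grid A [grid_spec()].
#' @return A data.frame with integer columns `row`, `col` (NA outside grid).
#' @export
point_to_cell <- function(x, y, grid) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1
  bad <- row < 1 | row > grid$nrows | col < 1 | col > grid$ncols |
    !is.finite(row) | !is.finite(col)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Map coordinates of cell centers
#' @param row,col Cell indices.
#' @param grid A [grid_spec()].
#' @return data.frame with columns `x`, `y`.
#' @export
cell_center <- function(row, col, grid) {
  data.frame(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
             y = grid$origin[2] + (row - 0.5) * grid$cell_size)
}

# Canonical 15-layer naming used throughout: 7 bioclimatic, 6 soil
# (2 categorical), 1 elevation.
STACK_LAYERS <- c("Bio02", "Bio03", "Bio05", "Bio08", "Bio14", "Bio15",
                  "Bio19", "Tece", "Tgravel", "Toc", "Tph", "Tsand",
                  "Drainage", "Tclass", "Elevation")
CLIMATE_LAYERS <- STACK_LAYERS[1:7]
SOIL_LAYERS <- STACK_LAYERS[8:14]
CATEGORICAL_LAYERS <- c("Drainage", "Tclass")

#' Assemble an environmental raster stack
#'
#' Binds named co-registered layers (matrices of identical shape) with a grid
#' and a sea/invalid mask into an `env_stack`. All layer values must be finite
#' on unmasked cells; categorical layers hold integer category codes.
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices, each `nrows x ncols`.
#' @param mask Logical matrix, `TRUE` marks sea / nodata cells.
#' @param kinds Named character vector, `"continuous"` or `"categorical"` per
#'   layer; defaults to categorical for `Drainage`/`Tclass`, else continuous.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, mask = NULL, kinds = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  for (nm in names(layers)) {
    lm <- layers[[nm]]
    if (!is.matrix(lm) || nrow(lm) != grid$nrows || ncol(lm) != grid$ncols)
      stop(sprintf("layer %s does not match the grid shape", nm))
  }
  if (is.null(mask)) mask <- matrix(FALSE, grid$nrows, grid$ncols)
  if (!is.logical(mask) || nrow(mask) != grid$nrows || ncol(mask) != grid$ncols)
    stop("mask must be a logical matrix matching the grid")
  if (is.null(kinds)) {
    kinds <- ifelse(names(layers) %in% CATEGORICAL_LAYERS,
                    "categorical", "continuous")
    names(kinds) <- names(layers)
  }
  kinds <- kinds[names(layers)]
  for (nm in names(layers)) {
    v <- layers[[nm]][!mask]
    if (any(!is.finite(v)))
      stop(sprintf("layer %s has non-finite values on unmasked cells", nm))
  }
  structure(list(grid = grid, layers = layers, mask = mask, kinds = kinds),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers on a %d x %d grid (%d unmasked cells)\n",
              length(x$layers), x$grid$nrows, x$grid$ncols, sum(!x$mask)))
  cat("  layers:", paste0(names(x$layers),
                          ifelse(x$kinds == "categorical", "*", "")), "\n")
  cat("  (* categorical)\n")
  invisible(x)
}

#' Layer values of unmasked cells as a table
#'
#' @param stack An [env_stack()].
#' @param cells Optional integer matrix/data.frame with columns `row`, `col`;
#'   default all unmasked cells.
#' @return data.frame with one column per layer plus `row`, `col`.
#' @export
stack_table <- function(stack, cells = NULL) {
  if (is.null(cells)) {
    idx <- which(!stack$mask, arr.ind = TRUE)
    cells <- data.frame(row = idx[, 1], col = idx[, 2])
  }
  lin <- cbind(cells$row, cells$col)
  out <- as.data.frame(lapply(stack$layers, function(m) m[lin]))
  names(out) <- names(stack$layers)
  cbind(cells[, c("row", "col")], out)
}

layer_kinds <- function(stack) stack$kinds

#' Read / write a single layer as ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, first file row = northernmost grid row.
#'
#' @param path File path.
#' @param values Numeric matrix (row 1 = south, as in [grid_spec()]).
#' @param grid A [grid_spec()].
#' @param mask Logical matrix of nodata cells, or NULL.
#' @param nodata Sentinel written for masked cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns `list(values, grid, mask)`.
#' @export
write_ascii_grid <- function(path, values, grid, mask = NULL, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$nrows,
            ncol(values) == grid$ncols)
  v <- values
  if (!is.null(mask)) v[mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncols),
               sprintf("nrows %d", grid$nrows),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g", grid$origin[2]),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  # file rows run north -> south
  for (r in seq(grid$nrows, 1L)) {
    writeLines(paste(format(v[r, ], trim = TRUE, digits = 9,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  nodata <- if (is.null(hdr$nodata_value)) NA_real_ else hdr$nodata_value
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc) stop("ASCII grid body size mismatch")
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # back to row 1 = south
  mask <- if (is.na(nodata)) matrix(FALSE, nr, nc) else m == nodata
  m[mask] <- NA_real_
  list(values = m,
       grid = grid_spec(nr, nc, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner)),
       mask = mask)
}

#' Write / read a whole stack as ASCII grids plus a YAML manifest
#'
#' One `.asc` file per layer and a `manifest.yaml` recording layer order,
#' kinds and grid geometry, so a stack round-trips losslessly.
#'
#' @param stack An [env_stack()].
#' @param dir Directory (created if needed).
#' @return `write_stack` returns the manifest path invisibly; `read_stack`
#'   returns an [env_stack()].
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_ascii_grid(file.path(dir, paste0(nm, ".asc")),
                     stack$layers[[nm]], stack$grid, stack$mask)
  manifest <- list(layers = as.list(names(stack$layers)),
                   kinds = as.list(unname(stack$kinds)),
                   grid = list(nrows = stack$grid$nrows,
                               ncols = stack$grid$ncols,
                               cell_size = stack$grid$cell_size,
                               origin = as.list(stack$grid$origin)))
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  nms <- unlist(manifest$layers)
  layers <- list(); mask <- NULL; grid <- NULL
  for (nm in nms) {
    g <- read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
    if (is.null(grid)) {
      grid <- g$grid; mask <- g$mask
    } else {
      if (!same_grid(grid, g$grid))
        stop("layer ", nm, " does not share the stack grid")
      mask <- mask | g$mask
    }
    layers[[nm]] <- g$values
  }
  for (nm in nms) layers[[nm]][mask] <- 0  # value under mask is irrelevant
  kinds <- unlist(manifest$kinds); names(kinds) <- nms
  env_stack(grid, layers, mask, kinds)
}
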