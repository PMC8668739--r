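#' Geographic grid specification
#'
#' Describes a north-up rectangular grid in geographic degrees. Rows run
#' north to south (row 1 is the northernmost), columns west to east.
#' Cell membership is half-open: a point lying exactly on a shared edge
#' belongs to the cell to its south-east.
#'
#' @param xmin Longitude of the western edge (degrees).
#' @param ymax Latitude of the northern edge (degrees).
#' @param cellsize Cell side length in degrees.
#' @param nrow,ncol Grid dimensions.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymax, cellsize, nrow, ncol) {
  stopifnot(cellsize > 0, nrow >= 1, ncol >= 1)
  structure(list(xmin = xmin, ymax = ymax, cellsize = cellsize,
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$ymax))
  invisible(x)
}

#' Coarsened grid specification
#'
#' @param grid A [grid_spec()].
#' @param factor Integer aggregation factor (fine cells per coarse cell side).
#' @return A `grid_spec` for the aggregated grid (ragged edges are kept as
#'   partial cells).
#' @export
coarsen_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "grid_spec"), factor >= 1)
  grid_spec(grid$xmin, grid$ymax, grid$cellsize * factor,
            ceiling(grid$nrow / factor), ceiling(grid$ncol / factor))
}

#' Cell centre coordinates
#'
#' @param grid A [grid_spec()].
#' @param row,col Integer row/column indices (vectorized).
#' @return Data frame with columns `lon`, `lat`.
#' @export
cell_center <- function(grid, row, col) {
  data.frame(lon = grid$xmin + (col - 0.5) * grid$cellsize,
             lat = grid$ymax - (row - 0.5) * grid$cellsize)
}

#' Locate points on a grid
#'
#' Half-open convention: a point on a shared edge is assigned to the cell to
#' its south-east.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Point coordinates (vectorized).
#' @return Data frame with columns `row`, `col`; `NA` for points off-grid.
#' @export
cell_of_point <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1L
  row <- floor((grid$ymax - lat) / grid$cellsize) + 1L
  # the southern/eastern outer boundary still belongs to the last cell
  col[lon == grid$xmin + grid$ncol * grid$cellsize] <- grid$ncol
  row[lat == grid$ymax - grid$nrow * grid$cellsize] <- grid$nrow
  bad <- col < 1L | col > grid$ncol | row < 1L | row > grid$nrow
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Environmental raster stack
#'
#' A set of aligned single-band rasters (matrices) sharing one [grid_spec()].
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param grid The shared `grid_spec`; dimensions must match the matrices.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, grid) {
  stopifnot(is.list(layers), length(layers) >= 1, inherits(grid, "grid_spec"))
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("env", seq_along(layers))
  for (l in layers)
    stopifnot(is.matrix(l), nrow(l) == grid$nrow, ncol(l) == grid$ncol)
  structure(list(layers = layers, grid = grid), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) [%s] on ", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Extract layer values at point locations
#'
#' @param env An [env_stack()].
#' @param lon,lat Point coordinates.
#' @return Matrix (points x layers) of layer values; `NA` rows for points
#'   falling outside the grid.
#' @export
extract_env <- function(env, lon, lat) {
  rc <- cell_of_point(env$grid, lon, lat)
  out <- sapply(env$layers, function(l) l[cbind(rc$row, rc$col)])
  out <- matrix(out, nrow = length(lon),
                dimnames = list(NULL, names(env$layers)))
  out
}

#' Block-maximum aggregation of a raster
#'
#' Assigns to each coarse cell the maximum value among the underlying
#' fine-resolution cells. Missing fine cells are ignored; an all-missing
#' block stays missing. Ragged edge blocks use the cells available.
#'
#' @param fine Numeric matrix (fine-resolution raster).
#' @param factor Integer aggregation factor (>= 1).
#' @return Matrix of dimension `ceiling(dim(fine)/factor)`.
#' @export
aggregate_max <- function(fine, factor) {
  stopifnot(is.matrix(fine), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(fine)
  nr <- ceiling(nrow(fine) / factor); nc <- ceiling(ncol(fine) / factor)
  ri <- (seq_len(nrow(fine)) - 1L) %/% factor + 1L
  ci <- (seq_len(ncol(fine)) - 1L) %/% factor + 1L
  out <- matrix(NA_real_, nr, nc)
  mx <- tapply(as.vector(fine), list(ri[row(fine)], ci[col(fine)]),
               function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  out[seq_len(nr), seq_len(nc)] <- mx
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format readable by standard GIS tools.
#'
#' @param mat Numeric matrix (row 1 = northernmost).
#' @param grid A [grid_spec()] matching `mat`.
#' @param path Output file path.
#' @param digits Significant digits written.
#' @export
write_asc <- function(mat, grid, path, digits = 8) {
  stopifnot(nrow(mat) == grid$nrow, ncol(mat) == grid$ncol)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - grid$nrow * grid$cellsize),
    sprintf("cellsize %.10g", grid$cellsize),
    "NODATA_value -9999"), con)
  m <- mat
  m[is.na(m)] <- -9999
  writeLines(apply(m, 1, function(r) paste(signif(r, digits), collapse = " ")),
             con)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_asc()] or any GIS.
#' @return List with `mat` (matrix, `NA` for NODATA) and `grid`
#'   ([grid_spec()]).
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  mat <- do.call(rbind, vals)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mat[mat == nodata] <- NA_real_
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    hdr$cellsize, hdr$nrows, hdr$ncols)
  list(mat = mat, grid = grid)
}
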