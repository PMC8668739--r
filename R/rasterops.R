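#' Presence-absence matrix over a coarse grid
#'
#' Cells x species binary occupancy. Rows are all cells of the coarse grid
#' (occupied or not); empty cells are excluded later by the index and
#' turnover layers as needed.
#'
#' @param mat Binary matrix, cells x species, with species column names.
#' @param coords Data frame with one row per cell: `cell`, `row`, `col`,
#'   `lon`, `lat` (cell centres).
#' @param grid The coarse [grid_spec()].
#' @return An object of class `pa_matrix`.
#' @export
pa_matrix <- function(mat, coords, grid) {
  stopifnot(is.matrix(mat), nrow(mat) == nrow(coords),
            all(mat %in% c(0, 1)), !is.null(colnames(mat)))
  rownames(mat) <- coords$cell
  structure(list(mat = mat, coords = coords, grid = grid), class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("pa_matrix: %d cells x %d species (%d occupied cells, fill %.2f%%)\n",
              nrow(x$mat), ncol(x$mat), sum(rowSums(x$mat) > 0),
              100 * mean(x$mat)))
  invisible(x)
}

#' Per-species range sizes
#'
#' Number of occupied cells per species on the current extent.
#'
#' @param pam A [pa_matrix()].
#' @return Named integer vector.
#' @export
range_sizes <- function(pam) colSums(pam$mat)

grid_coords <- function(grid) {
  rc <- expand.grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
  rc <- rc[order(rc$row, rc$col), , drop = FALSE]
  cc <- cell_center(grid, rc$row, rc$col)
  data.frame(cell = sprintf("r%02dc%02d", rc$row, rc$col),
             row = rc$row, col = rc$col, lon = cc$lon, lat = cc$lat,
             stringsAsFactors = FALSE)
}

#' Assemble a presence-absence matrix from per-species binary rasters
#'
#' Species whose binary map is empty everywhere are dropped with a warning
#' (they have no predicted cells on this extent).
#'
#' @param binary_layers Named list of binary matrices on the coarse grid
#'   (`NA` treated as absence).
#' @param grid Coarse [grid_spec()].
#' @return A [pa_matrix()].
#' @export
build_pam <- function(binary_layers, grid) {
  stopifnot(length(binary_layers) >= 1, !is.null(names(binary_layers)))
  coords <- grid_coords(grid)
  cols <- lapply(binary_layers, function(m) {
    stopifnot(nrow(m) == grid$nrow, ncol(m) == grid$ncol)
    v <- as.numeric(m[cbind(coords$row, coords$col)])
    v[is.na(v)] <- 0
    v
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(binary_layers)
  empty <- colSums(mat) == 0
  if (any(empty)) {
    warning("dropping species with no occupied cells: ",
            paste(names(binary_layers)[empty], collapse = ", "))
    mat <- mat[, !empty, drop = FALSE]
  }
  pa_matrix(mat, coords, grid)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Among candidate thresholds (the distinct observed scores), returns the
#' one maximizing sensitivity + specificity, where a score `>= t` counts as
#' predicted presence. Ties are broken toward the smallest such threshold.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return The selected threshold.
#' @export
threshold_maxsss <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(cand, function(t) mean(background_scores < t), 0)
  ss <- sens + spec
  cand[which(ss == max(ss))[1]]
}

#' Binarize a suitability raster at a threshold
#'
#' A cell counts as presence iff its value is `>=` the threshold and it lies
#' inside the optional mask. Missing cells are absence.
#'
#' @param coarse Numeric matrix of (aggregated) suitability.
#' @param threshold Finite threshold.
#' @param mask Optional logical matrix; `FALSE`/`NA` cells are forced absent.
#' @return Binary matrix.
#' @export
binarize <- function(coarse, threshold, mask = NULL) {
  stopifnot(is.finite(threshold))
  out <- (coarse >= threshold) * 1
  out[is.na(out)] <- 0
  if (!is.null(mask)) out[!mask | is.na(mask)] <- 0
  out
}

#' Rasterize occurrence points to a binary coarse-grid layer
#'
#' Fallback used when model predictions are unreliable for a species: the
#' raw presence locations are used instead. Cell membership follows the
#' half-open convention of [cell_of_point()].
#'
#' @param points Data frame with `lon`, `lat` for one species.
#' @param grid Coarse [grid_spec()].
#' @return Binary matrix; error if no point falls on the grid.
#' @export
points_to_binary <- function(points, grid) {
  rc <- cell_of_point(grid, points$lon, points$lat)
  ok <- !is.na(rc$row)
  if (!any(ok)) stop("no occurrence point falls inside the grid")
  out <- matrix(0, grid$nrow, grid$ncol)
  out[unique(cbind(rc$row[ok], rc$col[ok]))] <- 1
  out
}

# Parse "POLYGON((x y, x y, ...))" (single outer ring) into a 2-column matrix.
parse_wkt_polygon <- function(wkt) {
  body <- sub("(?i)^\\s*POLYGON\\s*\\(\\(", "", wkt, perl = TRUE)
  body <- sub("\\)\\).*$", "", body)
  xy <- do.call(rbind, lapply(strsplit(body, ",")[[1]], function(p) {
    as.numeric(strsplit(trimws(p), "\\s+")[[1]])
  }))
  if (ncol(xy) != 2 || nrow(xy) < 3) stop("malformed WKT polygon: ", wkt)
  xy
}

# Even-odd ray casting; points on an edge may fall either side (callers use
# cell centres, which are never on sensible region boundaries).
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Crop a presence-absence matrix to a region polygon
#'
#' Retains coarse cells whose centre lies inside the polygon and recomputes
#' per-species range sizes on the cropped extent; species left with no
#' occupied cell are dropped with a warning.
#'
#' @param pam A [pa_matrix()].
#' @param polygon A WKT `POLYGON` string or a 2-column matrix of ring
#'   vertices (lon, lat).
#' @return The cropped [pa_matrix()].
#' @export
crop_to_region <- function(pam, polygon) {
  poly <- if (is.character(polygon)) parse_wkt_polygon(polygon) else polygon
  keep <- point_in_polygon(pam$coords$lon, pam$coords$lat, poly)
  if (!any(keep)) stop("region polygon does not intersect the grid")
  mat <- pam$mat[keep, , drop = FALSE]
  coords <- pam$coords[keep, , drop = FALSE]
  gone <- colSums(mat) == 0
  if (any(gone)) {
    warning("species with no cells inside the region dropped: ",
            paste(colnames(mat)[gone], collapse = ", "))
    mat <- mat[, !gone, drop = FALSE]
  }
  pa_matrix(mat, coords, pam$grid)
}

#' Drop empty cells from a presence-absence matrix
#'
#' @param pam A [pa_matrix()].
#' @return A [pa_matrix()] restricted to cells with at least one species.
#' @export
drop_empty_cells <- function(pam) {
  keep <- rowSums(pam$mat) > 0
  pa_matrix(pam$mat[keep, , drop = FALSE], pam$coords[keep, , drop = FALSE],
            pam$grid)
}
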