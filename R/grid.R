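#' Lightweight geographic grid
#'
#' A `clim_grid` is a regular lon/lat grid in WGS84 holding one numeric
#' value per cell (`NA` = NoData).  Cells are half-open intervals
#' `[x, x + cellsize) x [y, y + cellsize)` so every point belongs to at
#' most one cell.  Values are stored as a matrix in map order: row 1 is
#' the northernmost row, column 1 the westernmost column (the layout of
#' the ESRI ASCII grid interchange format used by [write_ascii_grid()]).
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xmin,ymin coordinates of the lower-left corner, decimal degrees.
#' @param cellsize cell edge length in decimal degrees.
#' @return An object of class `clim_grid`.
#' @export
clim_grid <- function(values, xmin, ymin, cellsize) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(xmin), is.numeric(ymin), cellsize > 0)
  g <- structure(list(
    values = values,
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    cellsize = as.numeric(cellsize),
    nrow = nrow(values), ncol = ncol(values)
  ), class = "clim_grid")
  if (grid_xmax(g) > 180 + 1e-9 || g$ymin + g$nrow * g$cellsize > 90 + 1e-9)
    stop("grid extent exceeds valid WGS84 bounds")
  g
}

#' Grid definition helper
#'
#' Describes a grid without values; used by the raster builders and the
#' synthetic climate generator.
#'
#' @param xmin,ymin lower-left corner (decimal degrees).
#' @param ncol,nrow grid dimensions.
#' @param cellsize cell edge (decimal degrees).
#' @return A list of class `grid_def`.
#' @export
grid_def <- function(xmin, ymin, ncol, nrow, cellsize) {
  stopifnot(ncol >= 1, nrow >= 1, cellsize > 0)
  structure(list(xmin = xmin, ymin = ymin, ncol = as.integer(ncol),
                 nrow = as.integer(nrow), cellsize = cellsize),
            class = "grid_def")
}

#' @export
print.clim_grid <- function(x, ...) {
  cat(sprintf("<clim_grid> %d x %d cells of %g deg, x [%g, %g], y [%g, %g]\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, grid_xmax(x),
              x$ymin, grid_ymax(x)))
  cat(sprintf("  data cells: %d / %d\n", sum(!is.na(x$values)),
              length(x$values)))
  invisible(x)
}

grid_xmax <- function(g) g$xmin + g$ncol * g$cellsize
grid_ymax <- function(g) g$ymin + g$nrow * g$cellsize

empty_grid <- function(def) {
  clim_grid(matrix(NA_real_, def$nrow, def$ncol), def$xmin, def$ymin,
            def$cellsize)
}

#' Cell membership of points
#'
#' Returns the matrix row/column of the cell containing each point under
#' the half-open cell convention, or `NA` for points outside the extent.
#'
#' @param grid a [clim_grid()].
#' @param lon,lat point coordinates, decimal degrees.
#' @return data.frame with columns `row`, `col` (matrix indices, row 1 =
#'   north) and `inside`.
#' @export
cell_index <- function(grid, lon, lat) {
  ci <- floor((lon - grid$xmin) / grid$cellsize) + 1L
  rj <- floor((lat - grid$ymin) / grid$cellsize) + 1L   # row from bottom
  inside <- !is.na(lon) & !is.na(lat) &
    ci >= 1L & ci <= grid$ncol & rj >= 1L & rj <= grid$nrow
  ri <- grid$nrow - rj + 1L                             # row from top
  ri[!inside] <- NA_integer_; ci[!inside] <- NA_integer_
  data.frame(row = ri, col = ci, inside = inside)
}

#' Cell-center coordinates
#'
#' @param grid a [clim_grid()].
#' @param rows,cols matrix indices (row 1 = north); defaults to all cells.
#' @return data.frame with `lon`, `lat` of the requested cell centers.
#' @export
cell_centers <- function(grid, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    idx <- which(!is.na(grid$values) | is.na(grid$values), arr.ind = TRUE)
    rows <- idx[, 1]; cols <- idx[, 2]
  }
  lon <- grid$xmin + (cols - 0.5) * grid$cellsize
  lat <- grid$ymin + (grid$nrow - rows + 0.5) * grid$cellsize
  data.frame(lon = lon, lat = lat)
}

#' Extract grid values at point locations
#'
#' @param grid a [clim_grid()].
#' @param lon,lat point coordinates.
#' @return numeric vector of cell values; `NA` outside the extent or in
#'   NoData cells.
#' @export
grid_extract <- function(grid, lon, lat) {
  ix <- cell_index(grid, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- ix$inside
  out[ok] <- grid$values[cbind(ix$row[ok], ix$col[ok])]
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of values from north to south.
#'
#' @param path file path (conventionally `.asc`).
#' @return For `read_ascii_grid`, a [clim_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  clim_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param grid a [clim_grid()] to write.
#' @param nodata value used to encode `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol), sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  m <- grid$values
  m[is.na(m)] <- nodata
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " ")), con)
  invisible(path)
}
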