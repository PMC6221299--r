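#' Lightweight in-memory grid raster
#'
#' A minimal regular-grid raster: a numeric (or logical/integer) matrix plus
#' an origin and square cell size in projected meters. Rows index y from the
#' bottom (row 1 is the southernmost row), columns index x from the west.
#' This is the container every landscape and river layer in the package uses;
#' values are looked up by coordinate, not by index, in user-facing code.
#'
#' @param values matrix of cell values (rows = y from south, cols = x from west)
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m)
#' @param cellsize square cell edge length (m), > 0
#' @return an object of class `grid_raster`
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0) {
    stop("`cellsize` must be a single positive number")
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf(
    "<grid_raster> %d rows x %d cols, cell %g m, extent x [%g, %g] y [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, x$xmin + ncol(x$values) * x$cellsize,
    x$ymin, x$ymin + nrow(x$values) * x$cellsize
  ))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

raster_ncol <- function(r) ncol(r$values)
raster_nrow <- function(r) nrow(r$values)

#' Raster extent
#' @param r a `grid_raster`
#' @return named numeric `c(xmin, xmax, ymin, ymax)`
#' @export
raster_extent <- function(r) {
  c(
    xmin = r$xmin, xmax = r$xmin + raster_ncol(r) * r$cellsize,
    ymin = r$ymin, ymax = r$ymin + raster_nrow(r) * r$cellsize
  )
}

## row/col of coordinates; NA outside the grid
raster_rowcol <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- floor((y - r$ymin) / r$cellsize) + 1L
  bad <- col < 1L | col > raster_ncol(r) | row < 1L | row > raster_nrow(r) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Look up raster values at coordinates
#'
#' @param r a `grid_raster`
#' @param x,y coordinate vectors (m); recycled to common length
#' @return vector of cell values; `NA` outside the grid
#' @export
raster_value <- function(r, x, y) {
  rc <- raster_rowcol(r, x, y)
  out <- rep(r$values[1][NA], nrow(rc))
  ok <- !is.na(rc[, 1L])
  out[ok] <- r$values[cbind(rc[ok, 1L], rc[ok, 2L])]
  out
}

## column-major linear cell index of coordinates (matches as.vector order);
## NA outside the grid
raster_cell_index <- function(r, x, y) {
  rc <- raster_rowcol(r, x, y)
  (rc[, 2L] - 1L) * raster_nrow(r) + rc[, 1L]
}

## cell-center coordinate of column / row indices
raster_col_x <- function(r, col) r$xmin + (col - 0.5) * r$cellsize
raster_row_y <- function(r, row) r$ymin + (row - 0.5) * r$cellsize

#' Cell-center coordinates of every cell
#'
#' Cells are enumerated column-major over the value matrix (the same order as
#' `as.vector(r$values)`), so `cell_centers(r)$x[i]` pairs with
#' `as.vector(r$values)[i]`.
#'
#' @param r a `grid_raster`
#' @return data.frame with columns `x`, `y`
#' @export
cell_centers <- function(r) {
  nr <- raster_nrow(r)
  nc <- raster_ncol(r)
  data.frame(
    x = raster_col_x(r, rep(seq_len(nc), each = nr)),
    y = raster_row_y(r, rep(seq_len(nr), times = nc))
  )
}

#' Write / read a grid raster as an ESRI ASCII grid
#'
#' Plain-text interchange format for the package's rasters. `NA` is written as
#' the nodata value. Logical rasters round-trip as 0/1.
#'
#' @param r a `grid_raster`
#' @param path file path
#' @param nodata value standing for `NA` in the file
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `grid_raster`
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  storage.mode(v) <- "double"
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  ## ASCII grids are written north to south
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1L)
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- tolower(key)
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = val[["nrows"]], byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA
  grid_raster(m, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}
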