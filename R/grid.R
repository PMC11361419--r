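#' Define an equal-area analysis grid
#'
#' The pipeline works on an abstract equal-area grid in kilometre
#' coordinates: every cell is a `cell_km` x `cell_km` square, so cell area is
#' exactly `cell_km^2` and range sizes in km^2 are integer multiples of it.
#' This mirrors the convention of projecting ranges onto a 10 x 10 km
#' equal-area (Mollweide-style) grid before any areal accounting.
#'
#' Cells are indexed row-major and 0-based: cell `i` sits at row
#' `i %/% cols`, column `i %% cols` (both 0-based), and is identified by its
#' centre point. The grid origin (0, 0) is the outer corner of cell 0; row 0
#' is the bottom row.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param cell_km Cell edge length in km (default 10, i.e. 100 km^2 cells).
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(20, 30)
#' cell_area_km2(g)
#' @export
grid_spec <- function(rows, cols, cell_km = 10) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1) {
    abort("`rows` and `cols` must be positive counts.", class = "riskfill_config_error")
  }
  if (!is.numeric(cell_km) || cell_km <= 0) {
    abort("`cell_km` must be a positive length.", class = "riskfill_config_error")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols), cell_km = cell_km),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g km (%g km^2 each), extent %g x %g km\n",
    x$rows, x$cols, x$cell_km, x$cell_km^2, x$cols * x$cell_km, x$rows * x$cell_km
  ))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
n_cells <- function(grid) grid$rows * grid$cols

#' @rdname grid_spec
#' @export
cell_area_km2 <- function(grid) grid$cell_km^2

#' Cell index arithmetic
#'
#' Convert between 0-based row-major cell indices, (row, col) pairs and
#' centre coordinates in km.
#'
#' @param grid A [grid_spec()].
#' @param cell Integer vector of 0-based cell indices.
#' @param row,col 0-based row and column indices.
#' @param x,y Coordinates in km.
#' @return `cell_centers()` returns a tibble with `cell`, `row`, `col`,
#'   `x`, `y`; the converters return integer vectors.
#' @export
cell_from_rowcol <- function(grid, row, col) {
  as.integer(row) * grid$cols + as.integer(col)
}

#' @rdname cell_from_rowcol
#' @export
cell_to_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  tibble::tibble(cell = cell, row = cell %/% grid$cols, col = cell %% grid$cols)
}

#' @rdname cell_from_rowcol
#' @export
cell_from_xy <- function(grid, x, y) {
  col <- pmin(pmax(floor(x / grid$cell_km), 0), grid$cols - 1L)
  row <- pmin(pmax(floor(y / grid$cell_km), 0), grid$rows - 1L)
  cell_from_rowcol(grid, row, col)
}

#' @rdname cell_from_rowcol
#' @export
cell_centers <- function(grid, cell = seq_len(n_cells(grid)) - 1L) {
  rc <- cell_to_rowcol(grid, cell)
  dplyr::mutate(rc,
    x = (.data$col + 0.5) * grid$cell_km,
    y = (.data$row + 0.5) * grid$cell_km
  )
}
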