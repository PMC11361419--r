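#' Quadrant-split convex-hull range polygons
#'
#' A species' range is sketched as the convex polygon around its occurrence
#' points — split into up to four independent hulls by a vertical and a
#' horizontal line (the "quadrants"), so that a species occurring in two
#' disjoint basins or hemispheres is not bridged by one global hull.
#'
#' Quadrants holding one or two points, or only collinear points, cannot
#' support a two-dimensional hull; their points are buffered by half a cell
#' (`buffer_km`) into small squares and the hull of the buffered corners is
#' used, so sparsely observed species still obtain a minimal range.
#'
#' @param occurrences A data frame with `x`, `y` in km (a single species'
#'   points), or a matrix with two columns.
#' @param split_x,split_y Coordinates of the vertical / horizontal split
#'   lines in km. Points with `x < split_x` fall in the western quadrants;
#'   `y < split_y` in the southern ones.
#' @param buffer_km Buffer half-width for degenerate quadrants (typically
#'   half the grid cell edge).
#' @return A tibble with one row per nonempty quadrant: `quadrant`
#'   (`"SW"`, `"SE"`, `"NW"`, `"NE"`), `n_points`, and `polygon`, a
#'   list-column of two-column matrices of hull vertices in counterclockwise
#'   order.
#' @examples
#' pts <- data.frame(x = c(0, 4, 0), y = c(0, 0, 3))
#' hull_by_quadrant(pts, split_x = 100, split_y = 100)
#' @export
hull_by_quadrant <- function(occurrences, split_x, split_y, buffer_km = 5) {
  pts <- as.matrix(as.data.frame(occurrences)[, c("x", "y")])
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  if (nrow(pts) < 2) {
    abort("At least 2 distinct occurrence points are required to build a range.",
          class = "riskfill_insufficient_data")
  }
  qx <- ifelse(pts[, 1] < split_x, "W", "E")
  qy <- ifelse(pts[, 2] < split_y, "S", "N")
  quad <- paste0(qy, qx)
  out <- purrr::map_dfr(unique(quad), function(q) {
    p <- pts[quad == q, , drop = FALSE]
    tibble::tibble(quadrant = q, n_points = nrow(p),
                   polygon = list(quadrant_polygon(p, buffer_km)))
  })
  dplyr::arrange(out, .data$quadrant)
}

# hull if 2-dimensional, else buffered-square hull
quadrant_polygon <- function(p, buffer_km) {
  if (nrow(p) >= 3) {
    h <- grDevices::chull(p)        # clockwise indices
    poly <- p[rev(h), , drop = FALSE]
    if (polygon_area(poly) > 0) return(poly)
  }
  corners <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    cbind(p[i, 1] + c(-1, 1, 1, -1) * buffer_km,
          p[i, 2] + c(-1, -1, 1, 1) * buffer_km)
  }))
  h <- grDevices::chull(corners)
  corners[rev(h), , drop = FALSE]
}

#' Shoelace area of a simple polygon
#' @param poly Two-column matrix of vertices.
#' @return Area (nonnegative for counterclockwise vertex order as produced
#'   by [hull_by_quadrant()]).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Boundary-inclusive point-in-convex-polygon test (half-plane form).
# Vertices counterclockwise; a point is inside iff it is left of (or on)
# every edge, within a small tolerance scaled to the polygon extent.
points_in_convex <- function(px, py, poly) {
  n <- nrow(poly)
  if (n < 3) return(rep(FALSE, length(px)))
  eps <- 1e-9 * max(abs(poly), 1)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
             (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    inside <- inside & (cross >= -eps)
  }
  inside
}

#' Rasterize range polygons onto the analysis grid
#'
#' A cell belongs to the range iff its centre lies inside (or on the
#' boundary of) any of the polygons. Polygons falling entirely outside the
#' grid extent yield no cells (with a warning), not an error.
#'
#' @param polygons Output of [hull_by_quadrant()] (the `polygon`
#'   list-column is what is consumed), or a bare list of vertex matrices.
#' @param grid A [grid_spec()].
#' @return Sorted integer vector of occupied 0-based cell indices.
#' @export
rasterize_polygons <- function(polygons, grid) {
  polys <- if (is.data.frame(polygons)) polygons$polygon else polygons
  if (!length(polys)) return(integer(0))
  cells <- integer(0)
  for (poly in polys) {
    # candidate cells from the polygon bounding box only
    c0 <- max(floor(min(poly[, 1]) / grid$cell_km - 0.5), 0)
    c1 <- min(ceiling(max(poly[, 1]) / grid$cell_km), grid$cols - 1L)
    r0 <- max(floor(min(poly[, 2]) / grid$cell_km - 0.5), 0)
    r1 <- min(ceiling(max(poly[, 2]) / grid$cell_km), grid$rows - 1L)
    if (c1 < c0 || r1 < r0) next
    cand <- expand.grid(col = c0:c1, row = r0:r1)
    cx <- (cand$col + 0.5) * grid$cell_km
    cy <- (cand$row + 0.5) * grid$cell_km
    hit <- points_in_convex(cx, cy, poly)
    cells <- c(cells, cell_from_rowcol(grid, cand$row[hit], cand$col[hit]))
  }
  if (!length(cells)) {
    warn("Polygon set intersects no cell centre; returning an empty range.")
  }
  sort(unique(cells))
}

#' Build range rasters for a whole species pool
#'
#' For each species with at least 2 distinct occurrence points:
#' quadrant-split hulls ([hull_by_quadrant()]), rasterization
#' ([rasterize_polygons()]), plus the cells containing the occurrence
#' points themselves (so every observation is covered before depth
#' refinement). Species with fewer points are flagged unbuildable and
#' omitted from the range set.
#'
#' @param pool A [sample_species()] pool (or a list with `species` and
#'   `occurrences` tibbles).
#' @param world A [build_world()] world supplying the grid.
#' @param split_x,split_y Quadrant split lines in km; default the grid
#'   midlines (the synthetic analogue of the equator and the
#'   Atlantic/Pacific divide).
#' @return A `range_set`: tibble (`species_id`, `cell`) with the grid spec
#'   attached as attribute `grid`; unbuildable species ids in attribute
#'   `unbuildable`.
#' @export
build_ranges <- function(pool, world, split_x = NULL, split_y = NULL) {
  grid <- world$grid
  split_x <- split_x %||% (grid$cols * grid$cell_km / 2)
  split_y <- split_y %||% (grid$rows * grid$cell_km / 2)
  occ_split <- split(pool$occurrences, pool$occurrences$species_id)
  unbuildable <- character(0)
  res <- purrr::map(occ_split, function(o) {
    if (nrow(unique(o[, c("x", "y")])) < 2) return(NULL)
    polys <- hull_by_quadrant(o, split_x, split_y, buffer_km = grid$cell_km / 2)
    # a hair-thin buffered polygon may miss every centre; the occurrence
    # cells added below guarantee a nonempty range regardless
    cells <- suppressWarnings(rasterize_polygons(polys, grid))
    union(cells, cell_from_xy(grid, o$x, o$y))
  })
  ok <- !vapply(res, is.null, logical(1))
  unbuildable <- names(res)[!ok]
  tb <- tibble::tibble(
    species_id = rep(names(res)[ok], lengths(res[ok])),
    cell = as.integer(unlist(res[ok], use.names = FALSE))
  )
  new_range_set(dplyr::arrange(tb, .data$species_id, .data$cell), grid, unbuildable)
}

new_range_set <- function(tb, grid, unbuildable = character(0)) {
  structure(tb, grid = grid, unbuildable = unbuildable,
            class = c("range_set", class(tb)))
}

#' @export
print.range_set <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<range_set> %d species on a %d x %d grid (%g km cells)\n",
              dplyr::n_distinct(x$species_id), g$rows, g$cols, g$cell_km))
  NextMethod()
}

#' Range sizes in cells and km^2
#'
#' Cell area is exactly `cell_km^2`, so `area_km2 = n_cells * cell_km^2`;
#' e.g. on a 10 km grid a 149-cell range measures 14,900 km^2.
#'
#' @param ranges A `range_set` from [build_ranges()] (or any tibble with
#'   `species_id`, `cell` plus a `grid` attribute).
#' @return Tibble `species_id`, `n_cells`, `area_km2`.
#' @export
range_sizes <- function(ranges) {
  grid <- attr(ranges, "grid")
  dplyr::count(tibble::as_tibble(ranges), .data$species_id, name = "n_cells") |>
    dplyr::mutate(area_km2 = .data$n_cells * cell_area_km2(grid))
}

#' Refine ranges by species depth limits
#'
#' Removes cells whose maximal depth lies outside the species' known depth
#' interval — a cell survives iff `dmin <= depth(cell) <= dmax`. Never adds
#' cells. A missing bound on either side is treated as unconstrained.
#'
#' @param ranges A `range_set`.
#' @param world The world providing the aligned depth layer (or a numeric
#'   per-cell depth vector of length `n_cells(grid)`).
#' @param depth_limits Tibble `species_id`, `depth_min_m`, `depth_max_m`
#'   (e.g. columns of the pool's species table).
#' @return A `range_set` with the surviving cells; species emptied by the
#'   refinement are recorded in attribute `emptied`.
#' @export
depth_refine <- function(ranges, world, depth_limits) {
  grid <- attr(ranges, "grid")
  depth <- if (is.numeric(world)) world else depth_vector(world)
  if (length(depth) != n_cells(grid)) {
    abort("Depth layer is not aligned to the range grid.",
          class = "riskfill_alignment_error")
  }
  lim <- dplyr::select(depth_limits, "species_id",
                       dmin = "depth_min_m", dmax = "depth_max_m")
  tb <- dplyr::left_join(tibble::as_tibble(ranges), lim, by = "species_id") |>
    dplyr::mutate(
      d = depth[.data$cell + 1L],
      keep = (is.na(.data$dmin) | .data$d >= .data$dmin) &
             (is.na(.data$dmax) | .data$d <= .data$dmax)
    )
  kept <- dplyr::filter(tb, .data$keep) |> dplyr::select("species_id", "cell")
  emptied <- setdiff(unique(tb$species_id), unique(kept$species_id))
  new_range_set(kept, grid, attr(ranges, "unbuildable")) |>
    structure(emptied = emptied)
}

#' Write / read a range set as sparse CSV
#' @param ranges A `range_set`.
#' @param path CSV path (`species_id`, `cell`).
#' @param grid Grid to attach on read.
#' @export
write_ranges <- function(ranges, path) {
  readr::write_csv(tibble::as_tibble(ranges), path)
  invisible(path)
}

#' @rdname write_ranges
#' @export
read_ranges <- function(path, grid) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  new_range_set(dplyr::mutate(tb, cell = as.integer(.data$cell)), grid)
}
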