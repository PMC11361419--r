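#' Configure a synthetic ocean world
#'
#' A world is an equal-area grid carrying two layers: a maximal-depth raster
#' (one depth value per cell, in metres, positive downwards) and a boolean
#' protected-area (PA) mask. Worlds stand in for the real bathymetry and
#' protected-area layers so that every downstream stage — range building,
#' depth refinement, gap analysis, prioritization — can be exercised without
#' any download.
#'
#' @param grid_rows,grid_cols Grid dimensions.
#' @param cell_km Cell edge in km (default 10).
#' @param pa_fraction Expected fraction of cells that are protected, in
#'   \[0, 1\]. Cells are protected independently with this probability.
#' @param depth_range_m Length-2 nonnegative vector `(min, max)` bounding the
#'   per-cell maximal depth (metres).
#' @param seed Integer master seed; all world randomness derives from it.
#' @return A `world_config` list.
#' @export
world_config <- function(grid_rows, grid_cols, cell_km = 10,
                         pa_fraction = 0.1,
                         depth_range_m = c(0, 2000),
                         seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) {
    abort("Grid dimensions must be positive.", class = "riskfill_config_error")
  }
  if (pa_fraction < 0 || pa_fraction > 1) {
    abort("`pa_fraction` must lie in [0, 1].", class = "riskfill_config_error")
  }
  if (length(depth_range_m) != 2 || any(depth_range_m < 0) ||
      depth_range_m[1] > depth_range_m[2]) {
    abort("`depth_range_m` must be nonnegative (min, max).", class = "riskfill_config_error")
  }
  structure(
    list(
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      cell_km = cell_km, pa_fraction = pa_fraction,
      depth_range_m = depth_range_m, seed = as.integer(seed)
    ),
    class = "world_config"
  )
}

#' Build a synthetic world from its configuration
#'
#' Deterministic given the seed. The depth layer is a smooth latitudinal
#' gradient (shallow at the grid edges, deep in the middle) plus lognormal
#' roughness, rescaled into `depth_range_m`; the PA mask is independent
#' Bernoulli per cell with probability `pa_fraction`.
#'
#' Stage seeds are derived from the master seed in the fixed order
#' depth-layer, PA-mask.
#'
#' @param config A [world_config()].
#' @return A `riskfill_world`: list with `grid` ([grid_spec()]), `depth`
#'   (rows x cols matrix, metres), `pa` (logical rows x cols matrix), and the
#'   originating `config`. Use [as_tibble()][tibble::as_tibble] for a
#'   per-cell tidy view.
#' @examples
#' w <- build_world(world_config(20, 20, pa_fraction = 0.25, seed = 42))
#' mean(w$pa)
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  grid <- grid_spec(config$grid_rows, config$grid_cols, config$cell_km)
  seeds <- derive_seeds(config$seed, 2)

  set.seed(seeds[1])
  rows <- grid$rows; cols <- grid$cols
  lat <- (seq_len(rows) - 0.5) / rows            # 0..1 across rows
  basin <- sin(pi * lat)                         # deep mid-grid "basin"
  rough <- matrix(exp(rnorm(rows * cols, 0, 0.4)), rows, cols)
  depth_rel <- sweep(rough, 1, basin + 0.15, `*`)
  rng <- range(depth_rel)
  span <- config$depth_range_m[2] - config$depth_range_m[1]
  depth <- config$depth_range_m[1] +
    (depth_rel - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps) * span

  set.seed(seeds[2])
  pa <- matrix(runif(rows * cols) < config$pa_fraction, rows, cols)

  structure(
    list(grid = grid, depth = depth, pa = pa, config = config),
    class = "riskfill_world"
  )
}

#' @export
print.riskfill_world <- function(x, ...) {
  cat(sprintf(
    "<riskfill_world> %d x %d cells (%g km); depth %0.f-%0.f m; %.1f%% protected\n",
    x$grid$rows, x$grid$cols, x$grid$cell_km,
    min(x$depth), max(x$depth), 100 * mean(x$pa)
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble riskfill_world
#' @export
as_tibble.riskfill_world <- function(x, ...) {
  grid <- x$grid
  cc <- cell_centers(grid)
  # matrices are rows x cols with row 0 at matrix row 1
  dplyr::mutate(cc,
    depth_m = x$depth[cbind(.data$row + 1L, .data$col + 1L)],
    protected = x$pa[cbind(.data$row + 1L, .data$col + 1L)]
  )
}

#' Per-cell protected-area mask as a logical vector in cell-index order
#' @param world A `riskfill_world`.
#' @return Logical vector of length `n_cells(world$grid)`, index `i + 1`
#'   giving the mask of cell `i`.
#' @export
pa_mask_vector <- function(world) {
  as.vector(t(world$pa))
}

#' Per-cell maximal depth as a vector in cell-index order
#' @inheritParams pa_mask_vector
#' @export
depth_vector <- function(world) {
  as.vector(t(world$depth))
}
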