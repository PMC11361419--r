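test_that("quadrant hulls: single quadrant, shoelace area, dedup idempotence", {
  pts <- data.frame(x = c(0, 4, 0), y = c(0, 0, 3))
  h <- hull_by_quadrant(pts, split_x = 100, split_y = 100)
  expect_equal(nrow(h), 1)
  expect_equal(polygon_area(h$polygon[[1]]), 6)        # shoelace oracle

  dup <- rbind(pts, pts, pts[1, ])
  h2 <- hull_by_quadrant(dup, split_x = 100, split_y = 100)
  expect_equal(h$polygon, h2$polygon)

  expect_error(hull_by_quadrant(data.frame(x = 1, y = 1), 10, 10),
               class = "riskfill_insufficient_data")
})

test_that("points split across quadrants give independent hulls", {
  set.seed(7)
  pts <- data.frame(x = c(runif(5, 0, 40), runif(5, 60, 100)),
                    y = runif(10, 0, 40))
  h <- hull_by_quadrant(pts, split_x = 50, split_y = 50)
  expect_setequal(h$quadrant, c("SW", "SE"))
  # each polygon's vertices stay inside its own quadrant
  sw <- h$polygon[[match("SW", h$quadrant)]]
  se <- h$polygon[[match("SE", h$quadrant)]]
  expect_true(all(sw[, 1] < 50))
  expect_true(all(se[, 1] >= 50))
})

test_that("degenerate quadrants are buffered into minimal polygons", {
  pts <- data.frame(x = c(10, 30), y = c(10, 10))   # two collinear points
  h <- hull_by_quadrant(pts, split_x = 100, split_y = 100, buffer_km = 5)
  expect_equal(nrow(h), 1)
  expect_gt(polygon_area(h$polygon[[1]]), 0)
  # buffered hull covers both points
  expect_true(all(riskfill:::points_in_convex(pts$x, pts$y, h$polygon[[1]])))
})

test_that("rasterization: rectangle over a k x m block of centers, empty sets", {
  grid <- grid_spec(10, 10, cell_km = 10)
  # rectangle whose corners are the centers of cells (2,1) and (5,4):
  # boundary-inclusive center test -> exactly 4 x 4 cells
  rect <- cbind(c(15, 45, 45, 15), c(25, 25, 55, 55))
  cells <- rasterize_polygons(list(rect), grid)
  expect_equal(length(cells), 16)
  # brute-force center-in-rectangle oracle
  cc <- cell_centers(grid)
  oracle <- cc$cell[cc$x >= 15 & cc$x <= 45 & cc$y >= 25 & cc$y <= 55]
  expect_equal(cells, sort(oracle))

  expect_equal(rasterize_polygons(list(), grid), integer(0))
  far <- cbind(c(500, 510, 510), c(500, 500, 510))
  expect_warning(out <- rasterize_polygons(list(far), grid))
  expect_equal(out, integer(0))
})

test_that("rasterization matches the independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(11)
  for (rep in 1:12) {
    rows <- sample(5:20, 1); cols <- sample(5:20, 1)
    grid <- grid_spec(rows, cols, cell_km = 10)
    # random convex polygon: hull of jittered points (avoid knife-edge
    # boundary cases where the two implementations may disagree on ties)
    pts <- cbind(runif(8, 0, cols * 10) + 1e-3, runif(8, 0, rows * 10) + 1e-3)
    poly <- pts[rev(grDevices::chull(pts)), , drop = FALSE]
    expect_equal(rasterize_polygons(list(poly), grid),
                 oracle_rasterize(list(poly), grid))
  }
})

test_that("range sizes use exact cell-area arithmetic", {
  grid <- grid_spec(20, 20, cell_km = 10)
  rs <- make_range_set(list(spA = 0:148, spB = 5:9), grid)
  sizes <- range_sizes(rs)
  expect_equal(sizes$area_km2[sizes$species_id == "spA"], 14900)
  expect_equal(sizes$n_cells[sizes$species_id == "spA"], 149)
  expect_true(all(sizes$area_km2 %% cell_area_km2(grid) == 0))
})

test_that("depth refinement is monotone and honours the per-cell predicate", {
  w <- tiny_world(10, 10, pa_fraction = 0)
  grid <- w$grid
  depth <- depth_vector(w)
  rs <- make_range_set(list(sp1 = 0:99), grid)

  # bounds containing every cell depth: unchanged
  lim_all <- tibble::tibble(species_id = "sp1",
                            depth_min_m = min(depth), depth_max_m = max(depth))
  expect_equal(nrow(depth_refine(rs, w, lim_all)), 100)

  # bounds excluding every cell: emptied and flagged
  lim_none <- tibble::tibble(species_id = "sp1",
                             depth_min_m = max(depth) + 1,
                             depth_max_m = max(depth) + 2)
  r_none <- depth_refine(rs, w, lim_none)
  expect_equal(nrow(r_none), 0)
  expect_equal(attr(r_none, "emptied"), "sp1")

  # median split: surviving count equals the direct per-cell count
  med <- stats::median(depth)
  lim_half <- tibble::tibble(species_id = "sp1",
                             depth_min_m = med, depth_max_m = max(depth))
  kept <- depth_refine(rs, w, lim_half)
  expect_equal(nrow(kept), sum(depth >= med))
  expect_true(all(kept$cell %in% rs$cell))   # never adds cells

  bad_depth <- depth[-1]
  expect_error(depth_refine(rs, bad_depth, lim_all),
               class = "riskfill_alignment_error")
})

test_that("built ranges cover every occurrence cell before refinement", {
  w <- tiny_world(15, 15, seed = 33)
  pool <- tiny_pool(w, n_species = 40, seed = 44)
  ranges <- build_ranges(pool, w)
  occ_cells <- dplyr::distinct(
    dplyr::mutate(pool$occurrences, cell = cell_from_xy(w$grid, x, y)),
    species_id, cell)
  built <- dplyr::semi_join(occ_cells, tibble::as_tibble(ranges),
                            by = c("species_id", "cell"))
  covered <- occ_cells$species_id %in% attr(ranges, "unbuildable") |
    paste(occ_cells$species_id, occ_cells$cell) %in%
      paste(built$species_id, built$cell)
  expect_true(all(covered))
})
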