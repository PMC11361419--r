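# Shared fixtures and independent oracles, built in code at test time.

tiny_world <- function(rows = 20, cols = 20, pa_fraction = 0.2, seed = 101) {
  build_world(world_config(rows, cols, pa_fraction = pa_fraction, seed = seed))
}

tiny_pool <- function(world = tiny_world(), n_species = 120, seed = 202, ...) {
  sample_species(world, species_config(n_species = n_species, seed = seed, ...))
}

# range_set constructed directly from cells (bypasses the hull pipeline)
make_range_set <- function(cells_by_species, grid) {
  tb <- tibble::tibble(
    species_id = rep(names(cells_by_species), lengths(cells_by_species)),
    cell = as.integer(unlist(cells_by_species, use.names = FALSE))
  )
  structure(tb, grid = grid, unbuildable = character(0),
            class = c("range_set", class(tb)))
}

# Exhaustive greedy prioritization oracle: recomputes every cell value from
# scratch at every step, removing one lowest-valued cell at a time (ties ->
# lowest cell index). Independent of the package implementation.
oracle_removal_order <- function(cells_by_species, weights, unprotected,
                                 mode = "additive") {
  occ <- lapply(cells_by_species, intersect, unprotected)
  remaining <- sort(unprotected)
  removed <- integer(0)
  while (length(remaining)) {
    vals <- vapply(remaining, function(cl) {
      v <- 0; mx <- 0
      for (j in seq_along(occ)) {
        rem_j <- setdiff(occ[[j]], removed)
        if (length(rem_j) && cl %in% rem_j) {
          contrib <- weights[j] / length(rem_j)
          v <- v + contrib
          mx <- max(mx, contrib)
        }
      }
      if (mode == "additive") v else mx
    }, numeric(1))
    pick <- remaining[order(vals, remaining)][1]
    removed <- c(removed, pick)
    remaining <- setdiff(remaining, pick)
  }
  removed
}

# Independent point-in-polygon rasterization oracle via mgcv::in.out.
oracle_rasterize <- function(polys, grid) {
  cc <- cell_centers(grid)
  hit <- rep(FALSE, nrow(cc))
  for (poly in polys) {
    bnd <- rbind(poly, poly[1, ])
    hit <- hit | mgcv::in.out(bnd, cbind(cc$x, cc$y))
  }
  sort(cc$cell[hit])
}

# Small trait table with known structure for imputer tests.
structured_traits <- function(n = 150, seed = 1) {
  set.seed(seed)
  a <- runif(n, 0, 10)
  b <- a                              # exact copy of a
  noise <- rnorm(n)                   # independent of everything
  f1 <- factor(sample(c("x", "y"), n, replace = TRUE))
  f2 <- factor(ifelse(a > 5, "hi", "lo"))            # function of a
  const <- factor(rep("only", n), levels = "only")   # constant level
  tibble::tibble(species_id = sprintf("s%03d", seq_len(n)),
                 a = a, b = b, noise = noise, f1 = f1, f2 = f2, const = const)
}

# Balanced, strongly separable labeled pool: label is a noiseless threshold
# on one feature, other features pure noise.
separable_pool <- function(n = 200, seed = 1) {
  set.seed(seed)
  x1 <- runif(n)
  tibble::tibble(
    species_id = sprintf("s%04d", seq_len(n)),
    status = ifelse(x1 > stats::median(x1), "Threatened", "NonThreatened"),
    range_size = x1,
    noise1 = rnorm(n), noise2 = rnorm(n),
    noise_f = factor(sample(letters[1:3], n, replace = TRUE))
  )
}
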