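test_that("fixed weights follow the status scheme and sensitivity endpoints", {
  status <- tibble::tibble(
    species_id = c("a", "b", "c"),
    status = c("NonThreatened", "DDNE", "Threatened")
  )
  w <- assign_weights(status, mode = "fixed")
  expect_equal(w$weight, c(1, 2, 6))

  sens <- tibble::tibble(
    species_id = c("ev_t", "ev_nt", "pr_t_hi", "pr_t_lo", "pr_nt_hi",
                   "pr_nt_lo", "pr_ddne"),
    status = c("Threatened", "NonThreatened", "Threatened", "Threatened",
               "NonThreatened", "NonThreatened", "DDNE"),
    predicted = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    p = c(NA, NA, 1, 0.8, 1, 0.8, NA)
  )
  ws <- assign_weights(sens, mode = "sensitivity", tau = 0.8)
  expect_equal(ws$weight[ws$species_id == "ev_t"], 6)    # assessed keep 6
  expect_equal(ws$weight[ws$species_id == "ev_nt"], 1)
  expect_equal(ws$weight[ws$species_id == "pr_t_hi"], 5) # 2 + p on [2, 5]
  expect_equal(ws$weight[ws$species_id == "pr_t_lo"], 2)
  expect_equal(ws$weight[ws$species_id == "pr_nt_hi"], 1) # 2 - p on [1, 2]
  expect_equal(ws$weight[ws$species_id == "pr_nt_lo"], 2)
  expect_equal(ws$weight[ws$species_id == "pr_ddne"], 2)
  expect_true(all(ws$weight > 0))

  bad <- dplyr::mutate(sens, p = ifelse(species_id == "pr_t_hi", 0.5, p))
  expect_error(assign_weights(bad, mode = "sensitivity"),
               class = "riskfill_weighting_error")
})

test_that("uniform single-species ties resolve by lowest cell index", {
  grid <- grid_spec(1, 4, cell_km = 10)
  rs <- make_range_set(list(sp1 = 0:3), grid)
  rm_ <- zonation_rank(rs, c(sp1 = 1), rep(FALSE, 4), warp = 1)
  expect_equal(rm_$removal_order, 1:4)
  expect_equal(rm_$rank, c(0, 1/3, 2/3, 1))
})

test_that("greedy removal matches the exhaustive oracle on small instances", {
  set.seed(31)
  for (case in 1:25) {
    rows <- sample(2:4, 1); cols <- sample(2:4, 1)
    grid <- grid_spec(rows, cols, cell_km = 10)
    nc <- rows * cols
    n_sp <- sample(1:3, 1)
    cells_by_species <- lapply(seq_len(n_sp), function(j) {
      sort(sample(0:(nc - 1), sample(2:nc, 1)))
    })
    names(cells_by_species) <- paste0("sp", seq_len(n_sp))
    weights <- setNames(sample(c(1, 2, 6), n_sp, replace = TRUE),
                        names(cells_by_species))
    pa <- runif(nc) < 0.2
    if (all(pa)) pa[1] <- FALSE
    unprot <- which(!pa) - 1L
    for (mode in c("additive", "max_benefit")) {
      rs <- make_range_set(cells_by_species, grid)
      rm_ <- zonation_rank(rs, weights, pa, warp = 1, mode = mode)
      got <- rm_$cell[!rm_$protected][order(rm_$removal_order[!rm_$protected])]
      want <- oracle_removal_order(cells_by_species, weights, unprot, mode)
      expect_equal(got, want, info = paste("case", case, mode))
    }
  }
})

test_that("rank maps are complete permutations with protected cells masked", {
  w <- tiny_world(8, 8, pa_fraction = 0.25, seed = 41)
  pool <- tiny_pool(w, n_species = 15, seed = 42)
  rs <- build_ranges(pool, w)
  wts <- assign_weights(
    tibble::tibble(species_id = unique(rs$species_id), status = "DDNE"))
  rm_ <- zonation_rank(rs, wts, w, warp = 3)
  n_un <- sum(!rm_$protected)
  expect_setequal(rm_$removal_order[!rm_$protected], seq_len(n_un))
  expect_true(all(is.na(rm_$rank[rm_$protected])))
  expect_equal(sort(rm_$rank[!rm_$protected]), (0:(n_un - 1)) / (n_un - 1))
  # normalized rank strictly increases with removal order
  o <- order(rm_$removal_order[!rm_$protected])
  expect_true(all(diff(rm_$rank[!rm_$protected][o]) > 0))
  expect_error(zonation_rank(rs, wts, rep(TRUE, 64)),
               class = "riskfill_config_error")
})

test_that("rescaling all weights leaves the ranking unchanged", {
  grid <- grid_spec(3, 3, cell_km = 10)
  rs <- make_range_set(list(a = c(0, 1, 4), b = c(2, 4, 5, 8)), grid)
  pa <- rep(FALSE, 9)
  r1 <- zonation_rank(rs, c(a = 1, b = 3), pa)
  r2 <- zonation_rank(rs, c(a = 10, b = 30), pa)
  expect_equal(r1$removal_order, r2$removal_order)
})

test_that("warp removes blocks without intra-block recomputation", {
  # with warp = n_unprotected everything is removed in one sweep ordered by
  # the initial cell values (ties by index)
  grid <- grid_spec(2, 3, cell_km = 10)
  rs <- make_range_set(list(a = c(0, 1), b = c(1, 2, 3)), grid)
  pa <- rep(FALSE, 6)
  rm_ <- zonation_rank(rs, c(a = 1, b = 1), pa, warp = 6)
  v0 <- c(1/2, 1/2 + 1/3, 1/3, 1/3, 0, 0)   # initial additive values
  expect_equal(rm_$removal_order, order(order(v0, 0:5)))
})

test_that("delta ranks are zero on identical scenarios and antisymmetric", {
  w <- tiny_world(6, 6, pa_fraction = 0.2, seed = 51)
  grid <- w$grid
  rs <- make_range_set(list(a = 0:17, b = 18:35), grid)
  s1 <- tibble::tibble(species_id = c("a", "b"),
                       status = c("NonThreatened", "NonThreatened"))
  s2 <- tibble::tibble(species_id = c("a", "b"),
                       status = c("Threatened", "NonThreatened"))
  r1 <- zonation_rank(rs, assign_weights(s1), w)
  r2 <- zonation_rank(rs, assign_weights(s2), w)
  d0 <- delta_rank(r1, r1)
  expect_true(all(d0$delta[!d0$protected] == 0))
  d12 <- delta_rank(r1, r2)
  d21 <- delta_rank(r2, r1)
  expect_equal(d12$delta, -d21$delta)
  expect_true(all(is.na(d12$delta[d12$protected])))

  w2 <- tiny_world(6, 6, pa_fraction = 0.5, seed = 99)
  r3 <- zonation_rank(rs, assign_weights(s1), w2)
  expect_error(delta_rank(r1, r3), class = "riskfill_alignment_error")
})

test_that("upweighting a species raises the mean rank over its exclusive cells", {
  grid <- grid_spec(6, 6, cell_km = 10)
  # species a holds an exclusive block; species b covers the rest
  rs <- make_range_set(list(a = 0:8, b = 9:35), grid)
  pa <- rep(FALSE, 36)
  r_lo <- zonation_rank(rs, c(a = 1, b = 1), pa)
  r_hi <- zonation_rank(rs, c(a = 6, b = 1), pa)
  excl <- 0:8 + 1L
  expect_gte(mean(r_hi$rank[excl]), mean(r_lo$rank[excl]))
})
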