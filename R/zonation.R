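#' Status-based species weights for prioritization
#'
#' `mode = "fixed"`: Non-Threatened 1, DDNE 2, Threatened 6, regardless of
#' how the status was obtained.
#'
#' `mode = "sensitivity"` downweights model-predicted statuses relative to
#' assessed ones: assessed species keep the fixed weights; predicted
#' Threatened species get `2 + p` rescaled onto \[2, 5\] and predicted
#' Non-Threatened species `2 - p` rescaled onto \[1, 2\], where `p` is the
#' fraction of ensemble models supporting the call (admissible `p` lies in
#' `(tau, 1]`, so the rescaling maps `p = tau` to the low-confidence end);
#' species remaining DDNE get 2.
#'
#' @param status Tibble with `species_id`, `status` (over
#'   `c("Threatened", "NonThreatened", "DDNE")`) and, for sensitivity mode,
#'   logical `predicted` (TRUE where the status came from the model) and
#'   numeric `p` for predicted species.
#' @param mode `"fixed"` or `"sensitivity"`.
#' @param tau Consensus threshold bounding admissible `p` from below
#'   (default 0.8).
#' @param w_nt,w_ddne,w_t Fixed weights (defaults 1, 2, 6).
#' @return Tibble `species_id`, `weight` (> 0).
#' @export
assign_weights <- function(status, mode = c("fixed", "sensitivity"), tau = 0.8,
                           w_nt = 1, w_ddne = 2, w_t = 6) {
  mode <- match.arg(mode)
  fixed <- function(st) {
    dplyr::case_when(st == "Threatened" ~ w_t,
                     st == "NonThreatened" ~ w_nt,
                     .default = w_ddne)
  }
  if (mode == "fixed") {
    return(tibble::tibble(species_id = status$species_id,
                          weight = fixed(status$status)))
  }
  if (!all(c("predicted", "p") %in% names(status))) {
    abort("Sensitivity mode needs `predicted` and `p` columns.",
          class = "riskfill_weighting_error")
  }
  pred <- dplyr::coalesce(status$predicted, FALSE)
  p <- status$p
  if (any(pred & status$status != "DDNE" & (is.na(p) | p < tau | p > 1))) {
    abort("Predicted species need consensus support `p` in (tau, 1].",
          class = "riskfill_weighting_error")
  }
  unit <- (p - tau) / (1 - tau)             # affine map of (tau, 1] onto (0, 1]
  w <- dplyr::case_when(
    !pred ~ fixed(status$status),
    status$status == "Threatened" ~ 2 + 3 * unit,
    status$status == "NonThreatened" ~ 2 - unit,
    .default = w_ddne
  )
  tibble::tibble(species_id = status$species_id, weight = w)
}

#' Greedy cell-removal prioritization ranking
#'
#' Iteratively removes the lowest-valued unprotected cells and records the
#' removal order; cells removed last are the most valuable. The value of a
#' cell is the weighted sum (mode `"additive"`, the default) or the
#' weighted maximum (mode `"max_benefit"`, core-area style) of the
#' distribution fractions `q_ij` of the species present, where `q_ij` is
#' the cell's share of species `j`'s *remaining* distribution — so as a
#' species' range erodes, its surviving cells gain value. `warp` cells are
#' removed per iteration without intra-block recomputation; ties are broken
#' by removing the lowest cell index first. Protected cells are never
#' ranked, and by default never counted in the `q_ij` denominators.
#'
#' The final rank of a cell is its removal position normalized to \[0, 1\]:
#' `(position - 1) / (n_unprotected - 1)` — the least valuable cell gets 0,
#' the most valuable 1. Multiplying all weights by a constant leaves the
#' ranking unchanged.
#'
#' @param ranges A `range_set` of species distributions.
#' @param weights Tibble `species_id`, `weight` (positive), or a named
#'   vector.
#' @param world World carrying the protected mask (or a logical per-cell
#'   vector).
#' @param warp Cells removed per iteration (default 1; the global-scale
#'   setting in production runs is 1000).
#' @param mode `"additive"` or `"max_benefit"`.
#' @param include_protected_denominator Count protected cells in the
#'   `q_ij` denominators (default `FALSE`).
#' @return A `rank_map` tibble over all grid cells: `cell`, `row`, `col`,
#'   `protected`, `removal_order` (1 = removed first; `NA` for protected
#'   cells, which are outside the ranking), `rank` in \[0, 1\]. Every
#'   unprotected cell is ranked, occupied or not.
#' @export
zonation_rank <- function(ranges, weights, world, warp = 1,
                          mode = c("additive", "max_benefit"),
                          include_protected_denominator = FALSE) {
  mode <- match.arg(mode)
  if (warp < 1) abort("`warp` must be >= 1.", class = "riskfill_config_error")
  grid <- attr(ranges, "grid")
  pa <- if (is.logical(world)) world else pa_mask_vector(world)
  if (length(pa) != n_cells(grid)) {
    abort("Protected mask is not aligned to the range grid.",
          class = "riskfill_alignment_error")
  }
  if (is.data.frame(weights)) weights <- setNames(weights$weight, weights$species_id)
  if (any(weights <= 0)) abort("Weights must be positive.", class = "riskfill_weighting_error")

  unprot <- which(!pa) - 1L                  # 0-based cell ids
  if (!length(unprot)) abort("All cells are protected; nothing to rank.",
                             class = "riskfill_config_error")
  tb <- tibble::as_tibble(ranges)
  tb <- tb[tb$species_id %in% names(weights), , drop = FALSE]

  sp_ids <- unique(tb$species_id)
  sp_idx <- match(tb$species_id, sp_ids)
  w <- unname(weights[sp_ids])
  cell_pos <- match(tb$cell, unprot)         # position among unprotected, NA if protected
  denom_all <- tabulate(sp_idx, nbins = length(sp_ids))

  keep <- !is.na(cell_pos)
  M <- Matrix::sparseMatrix(i = cell_pos[keep], j = sp_idx[keep], x = 1,
                            dims = c(length(unprot), length(sp_ids)))
  n_rem <- if (include_protected_denominator) denom_all else Matrix::colSums(M)

  n_un <- length(unprot)
  order_out <- integer(n_un)                 # removal position per unprotected cell
  alive <- rep(TRUE, n_un)
  pos <- 0L
  trip <- Matrix::summary(M)                 # i (cell pos), j (species), x
  while (pos < n_un) {
    contrib <- ifelse(n_rem[trip$j] > 0, w[trip$j] / n_rem[trip$j], 0)
    live <- alive[trip$i]
    val <- numeric(n_un)
    if (mode == "additive") {
      agg <- rowsum(contrib[live], trip$i[live])
    } else {
      agg <- vapply(split(contrib[live], trip$i[live]), max, numeric(1))
      agg <- matrix(agg, dimnames = list(names(agg), NULL))
    }
    val[as.integer(rownames(agg))] <- agg[, 1]
    val[!alive] <- Inf
    take <- min(warp, sum(alive))
    ord <- order(val, seq_len(n_un))         # ties -> lowest index first
    sel <- ord[seq_len(take)]
    order_out[sel] <- pos + seq_len(take)
    alive[sel] <- FALSE
    if (!include_protected_denominator) {
      removed_counts <- tabulate(trip$j[trip$i %in% sel], nbins = length(sp_ids))
      n_rem <- n_rem - removed_counts
    }
    pos <- pos + take
  }

  rank_norm <- if (n_un > 1) (order_out - 1) / (n_un - 1) else rep(1, n_un)
  cc <- cell_centers(grid)
  out <- dplyr::mutate(cc,
    protected = pa[.data$cell + 1L],
    removal_order = NA_integer_,
    rank = NA_real_
  )
  out$removal_order[unprot + 1L] <- order_out
  out$rank[unprot + 1L] <- rank_norm
  structure(out, grid = grid, warp = warp, mode = mode,
            class = c("rank_map", class(out)))
}

#' @export
print.rank_map <- function(x, ...) {
  cat(sprintf("<rank_map> %d cells ranked (%d protected), mode %s, warp %d\n",
              sum(!x$protected), sum(x$protected), attr(x, "mode"), attr(x, "warp")))
  NextMethod()
}

#' Per-cell rank difference between two prioritization scenarios
#'
#' `rank_after - rank_before` for every unprotected cell; positive values
#' mark cells whose conservation priority rose under the second scenario.
#' Antisymmetric under swapping the scenarios. Both maps must share the
#' grid and the protected mask.
#'
#' @param before,after `rank_map`s from [zonation_rank()].
#' @return A `delta_rank_map` tibble: `cell`, `row`, `col`, `protected`,
#'   `rank_before`, `rank_after`, `delta` (NA for protected cells).
#' @export
delta_rank <- function(before, after) {
  gb <- attr(before, "grid"); ga <- attr(after, "grid")
  if (!identical(unclass(gb), unclass(ga)) ||
      !identical(before$protected, after$protected)) {
    abort("Scenarios differ in grid or protected mask.",
          class = "riskfill_alignment_error")
  }
  out <- tibble::tibble(
    cell = before$cell, row = before$row, col = before$col,
    protected = before$protected,
    rank_before = before$rank, rank_after = after$rank,
    delta = after$rank - before$rank
  )
  structure(out, grid = gb, class = c("delta_rank_map", class(out)))
}
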