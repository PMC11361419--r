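#' Log-linear species-specific conservation target rule
#'
#' Narrow-ranged species need proportionally more of their range protected
#' than widespread ones. The rule fixes two anchors — below `r_full` km^2 a
#' species needs `t_full` percent of its range protected, above `r_min` km^2
#' only `t_min` percent — and interpolates linearly in log10 range size
#' between them. Defaults: 100% below 10,000 km^2, 10% above 390,000 km^2.
#'
#' @param r_full,r_min Anchor range sizes in km^2 (`r_full < r_min`).
#' @param t_full,t_min Anchor targets in percent (`t_full > t_min`).
#' @return A `target_rule` with the derived slope and intercept of the line
#'   in (log10 km^2, percent) space.
#' @examples
#' rule <- target_rule()
#' conservation_target(c(10000, 390000, 62450), rule)
#' @export
target_rule <- function(r_full = 10000, r_min = 390000, t_full = 100, t_min = 10) {
  if (!(r_full < r_min)) abort("`r_full` must be below `r_min`.", class = "riskfill_config_error")
  if (!(t_full > t_min)) abort("`t_full` must exceed `t_min`.", class = "riskfill_config_error")
  slope <- (t_min - t_full) / (log10(r_min) - log10(r_full))
  intercept <- t_full - slope * log10(r_full)
  structure(list(r_full = r_full, r_min = r_min, t_full = t_full, t_min = t_min,
                 slope = slope, intercept = intercept),
            class = "target_rule")
}

#' @export
print.target_rule <- function(x, ...) {
  cat(sprintf("<target_rule> %g%% below %s km^2, %g%% above %s km^2 (log-linear between)\n",
              x$t_full, format(x$r_full, big.mark = ","),
              x$t_min, format(x$r_min, big.mark = ",")))
  invisible(x)
}

#' @rdname target_rule
#' @param range_km2 Positive range sizes in km^2 (vectorized).
#' @param rule A `target_rule`.
#' @return `conservation_target()`: target percentages in
#'   \[`t_min`, `t_full`\], clamped outside the anchors.
#' @export
conservation_target <- function(range_km2, rule = target_rule()) {
  if (any(range_km2 <= 0)) {
    abort("Range sizes must be positive.", class = "riskfill_domain_error")
  }
  raw <- rule$intercept + rule$slope * log10(range_km2)
  pmin(pmax(raw, rule$t_min), rule$t_full)
}

#' Protected-area coverage of species ranges
#'
#' Coverage is purely geometric: the percentage of a species' range cells
#' that fall inside the protected-area mask.
#'
#' @param ranges A `range_set` ([build_ranges()]).
#' @param world The world carrying the aligned PA mask (or a logical
#'   per-cell vector of length `n_cells(grid)`).
#' @return Tibble `species_id`, `n_cells`, `n_protected`, `coverage`
#'   (percent in \[0, 100\]). Species with empty ranges cannot appear in a
#'   `range_set`, so coverage is always defined.
#' @export
mpa_coverage <- function(ranges, world) {
  grid <- attr(ranges, "grid")
  pa <- if (is.logical(world)) world else pa_mask_vector(world)
  if (length(pa) != n_cells(grid)) {
    abort("PA mask is not aligned to the range grid.", class = "riskfill_alignment_error")
  }
  tibble::as_tibble(ranges) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_protected = sum(pa[.data$cell + 1L]),
      coverage = 100 * .data$n_protected / .data$n_cells,
      .groups = "drop"
    )
}

#' Target achievement
#'
#' Coverage divided by the species-specific target, in percent of the
#' required protection realized. Values above 100 are capped at 100 by
#' default; the uncapped value is always returned alongside.
#'
#' @param coverage,target Percent vectors (target must be positive).
#' @param cap Cap achievement at 100 (default `TRUE`).
#' @return Tibble `achievement`, `achievement_uncapped`.
#' @export
achievement <- function(coverage, target, cap = TRUE) {
  if (any(target <= 0)) abort("Targets must be positive.", class = "riskfill_domain_error")
  raw <- 100 * coverage / target
  tibble::tibble(
    achievement = if (cap) pmin(raw, 100) else raw,
    achievement_uncapped = raw
  )
}

#' Per-species gap analysis against the protected-area network
#'
#' Combines [mpa_coverage()], [conservation_target()] and [achievement()]
#' into one record per species, joined with a status table for group
#' comparisons.
#'
#' @param ranges A `range_set`.
#' @param world A world (PA mask + grid).
#' @param status Optional tibble `species_id`, `status` to join.
#' @param rule A [target_rule()].
#' @param cap Cap achievement at 100.
#' @return A `protection_record` tibble: `species_id`, `n_cells`,
#'   `area_km2`, `coverage`, `target`, `achievement`,
#'   `achievement_uncapped` (+ `status` when supplied).
#' @export
gap_analysis <- function(ranges, world, status = NULL, rule = target_rule(),
                         cap = TRUE) {
  grid <- attr(ranges, "grid")
  rec <- mpa_coverage(ranges, world) |>
    dplyr::mutate(
      area_km2 = .data$n_cells * cell_area_km2(grid),
      target = conservation_target(.data$area_km2, rule)
    )
  rec <- dplyr::bind_cols(rec, achievement(rec$coverage, rec$target, cap = cap))
  if (!is.null(status)) {
    rec <- dplyr::left_join(rec, dplyr::select(status, "species_id", "status"),
                            by = "species_id")
  }
  structure(rec, rule = rule, class = c("protection_record", class(rec)))
}

#' Rank tests of protection between status groups
#'
#' Kruskal–Wallis across three or more groups, Wilcoxon rank-sum for pairs,
#' plus pairwise Wilcoxon comparisons alongside the omnibus test.
#'
#' @param records A data frame (e.g. [gap_analysis()] output).
#' @param value Column to compare (default `"achievement"`).
#' @param group Grouping column (default `"status"`).
#' @return A tibble of tests: `comparison`, `method`, `statistic`, `df`
#'   (omnibus only), `p_value`.
#' @export
compare_protection_groups <- function(records, value = "achievement",
                                      group = "status") {
  df <- as.data.frame(records)
  g <- factor(df[[group]])
  v <- df[[value]]
  keep <- !is.na(g) & !is.na(v)
  g <- droplevels(g[keep]); v <- v[keep]
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    abort("Need at least 2 nonempty groups.", class = "riskfill_grouping_error")
  }
  out <- list()
  if (nlevels(g) >= 3) {
    kw <- kruskal.test(v, g)
    out[[1]] <- tibble::tibble(
      comparison = "omnibus", method = "kruskal-wallis",
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value
    )
  }
  prs <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- purrr::map_dfr(prs, function(pr) {
    wt <- suppressWarnings(wilcox.test(v[g == pr[1]], v[g == pr[2]]))
    tibble::tibble(
      comparison = paste(pr, collapse = " vs "), method = "wilcoxon",
      statistic = unname(wt$statistic), df = NA_real_, p_value = wt$p.value
    )
  })
  dplyr::bind_rows(out, pw)
}
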