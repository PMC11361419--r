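#' Relative feature importance across a forest ensemble
#'
#' Per-model impurity importances are averaged over all models and
#' normalized to percent of the total, giving one relative-importance
#' profile for the whole ensemble.
#'
#' @param ensemble A [fit_status_ensemble()] object with
#'   `algorithm = "rf"` (forests carry impurity importances).
#' @return An `importance_profile` tibble: `feature`,
#'   `importance_pct` (nonnegative, sums to 100), sorted decreasing.
#' @export
relative_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "status_ensemble"))
  if (ensemble$config$algorithm != "rf") {
    abort("Importance profiles require the forest ensemble.",
          class = "riskfill_schema_error")
  }
  imps <- purrr::map(ensemble$models, function(m) m$fit$variable.importance)
  nm <- names(imps[[1]])
  if (!all(purrr::map_lgl(imps, ~ identical(names(.x), nm)))) {
    abort("Models carry mixed feature schemas.", class = "riskfill_schema_error")
  }
  avg <- pmax(Reduce(`+`, imps) / length(imps), 0)
  out <- tibble::tibble(feature = nm, importance_pct = 100 * avg / sum(avg)) |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
  structure(out, class = c("importance_profile", class(out)))
}

#' Partial-dependence curve of the threat probability
#'
#' Standard partial dependence: for each grid value of the feature, the
#' feature is clamped to that value across the reference data, every model
#' predicts the probability of Threatened, and predictions are averaged
#' over rows and models.
#'
#' @param ensemble A [fit_status_ensemble()] object.
#' @param data Reference tibble carrying the ensemble's features.
#' @param feature Feature name (numeric features get an `n_grid`-point
#'   grid over their observed range; factors get one point per level).
#' @param n_grid Grid resolution for numeric features (default 50).
#' @return A `partial_curve` tibble: `feature`, `value`, `p_threat`
#'   (in \[0, 1\]).
#' @export
partial_dependence <- function(ensemble, data, feature, n_grid = 50) {
  stopifnot(inherits(ensemble, "status_ensemble"))
  if (!feature %in% ensemble$schema$features) {
    abort(paste0("Unknown feature: ", feature), class = "riskfill_schema_error")
  }
  x <- encode_features(data, ensemble$schema)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  col <- x[[feature]]
  grid_vals <- if (is.numeric(col)) {
    seq(min(col), max(col), length.out = n_grid)
  } else {
    levels(col)
  }
  p <- vapply(grid_vals, function(v) {
    xg <- x
    xg[[feature]] <- if (is.numeric(col)) v else factor(v, levels = levels(col))
    mean(purrr::map_dbl(ensemble$models, ~ mean(predict_prob_one(.x, xg))))
  }, numeric(1))
  out <- tibble::tibble(feature = feature,
                        value = if (is.numeric(col)) grid_vals else as.character(grid_vals),
                        p_threat = p)
  structure(out, class = c("partial_curve", class(out)))
}

# --- phylogenetic signal D --------------------------------------------------

# Sum of absolute sister-clade differences of a tip-valued trait: node
# values are the means of their daughters' values, accumulated postorder;
# each internal node contributes the absolute difference of its daughters
# (pairwise deviations from the node mean for soft polytomies).
d_sum <- function(tree, x) {
  ntip <- length(tree$tip.label)
  vals <- c(as.numeric(x), rep(NA_real_, tree$Nnode))
  edge <- tree$edge[ape::reorder.phylo(tree, "postorder", index.only = TRUE), ]
  total <- 0
  children <- split(edge[, 2], edge[, 1])
  for (node in unique(edge[, 1])) {
    kids <- children[[as.character(node)]]
    kv <- vals[kids]
    vals[node] <- mean(kv)
    total <- total + if (length(kv) == 2) abs(kv[1] - kv[2]) else sum(abs(kv - mean(kv)))
  }
  total
}

# Brownian tip values: independent normal increments along branches,
# applied root-first (reverse postorder).
brownian_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  vals <- numeric(ntip + tree$Nnode)
  ord <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  edge <- tree$edge[ord, , drop = FALSE]
  inc <- rnorm(nrow(edge), 0, sqrt(pmax(tree$edge.length[ord], 1e-12)))
  for (i in seq_len(nrow(edge))) {
    vals[edge[i, 2]] <- vals[edge[i, 1]] + inc[i]
  }
  vals[seq_len(ntip)]
}

#' Phylogenetic signal D for a binary trait
#'
#' The D statistic contrasts the observed sum of sister-clade differences
#' of a binary trait with two nulls: random shuffling of the tip labels
#' (phylogenetically random, D = 1 in expectation) and a Brownian process
#' thresholded to the observed prevalence (clumped, D = 0 in expectation):
#' `D = (d_obs - mean(d_brownian)) / (mean(d_random) - mean(d_brownian))`.
#'
#' With a list of trees (`multiPhylo`), D is estimated per tree and
#' summarized as mean and SD across trees.
#'
#' @param tree A rooted `phylo`, or a `multiPhylo` list of trees.
#' @param trait Named binary vector (0/1, logical, or two-level
#'   factor/character) over the tip labels; both classes must be present.
#' @param n_perm Permutation and Brownian replicates (default 1000).
#' @param seed Seed.
#' @return A `phylo_d` object; see [tidy.phylo_d()] / [glance.phylo_d()].
#' @examples
#' tr <- ape::rtree(32)
#' x <- setNames(rbinom(32, 1, 0.4), tr$tip.label)
#' phylo_d(tr, x, n_perm = 100, seed = 1)
#' @export
phylo_d <- function(tree, trait, n_perm = 1000, seed = 1L) {
  if (inherits(tree, "multiPhylo") || (is.list(tree) && !inherits(tree, "phylo"))) {
    seeds <- derive_seeds(seed, length(tree))
    ds <- purrr::map_dbl(seq_along(tree), function(i) {
      phylo_d(tree[[i]], trait, n_perm = n_perm, seed = seeds[i])$d
    })
    return(structure(
      list(d = mean(ds), d_sd = sd(ds), per_tree = ds,
           n_trees = length(ds), n_perm = n_perm),
      class = "phylo_d"
    ))
  }
  stopifnot(inherits(tree, "phylo"))
  x <- trait
  if (is.factor(x) || is.character(x)) {
    lv <- sort(unique(as.character(x)))
    if (length(lv) != 2) abort("Trait must be binary.", class = "riskfill_trait_error")
    x <- setNames(as.numeric(as.character(x) == lv[2]), names(trait))
  }
  x <- x[tree$tip.label]
  if (anyNA(x)) abort("Trait must cover every tip.", class = "riskfill_trait_error")
  if (length(unique(x)) < 2) {
    abort("D is undefined for a constant trait.", class = "riskfill_trait_error")
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (is.null(tree$edge.length)) tree <- ape::compute.brlen(tree)

  set.seed(seed)
  d_obs <- d_sum(tree, x)
  n1 <- sum(x)
  d_rand <- replicate(n_perm, d_sum(tree, sample(x)))
  # prevalence-matched Brownian null; averaging the two threshold
  # directions (top-n1 vs bottom-n1 tips as the "1" class) makes D exactly
  # invariant to swapping the 0/1 coding of the trait
  d_brown <- replicate(n_perm, {
    b <- brownian_tips(tree)
    hi <- as.numeric(b >= sort(b, decreasing = TRUE)[n1])
    lo <- as.numeric(b <= sort(b)[n1])
    (d_sum(tree, hi) + d_sum(tree, lo)) / 2
  })
  structure(
    list(d = (d_obs - mean(d_brown)) / (mean(d_rand) - mean(d_brown)),
         d_sd = NA_real_, per_tree = NULL, n_trees = 1L, n_perm = n_perm,
         d_obs = d_obs, d_rand_mean = mean(d_rand), d_brown_mean = mean(d_brown)),
    class = "phylo_d"
  )
}

#' @export
print.phylo_d <- function(x, ...) {
  if (x$n_trees > 1) {
    cat(sprintf("<phylo_d> D = %.3f +/- %.3f over %d trees (%d replicates each)\n",
                x$d, x$d_sd, x$n_trees, x$n_perm))
  } else {
    cat(sprintf("<phylo_d> D = %.3f (%d replicates)\n", x$d, x$n_perm))
  }
  invisible(x)
}

#' Tidiers for D-statistic results
#' @param x A [phylo_d()] result.
#' @param ... Unused.
#' @export
tidy.phylo_d <- function(x, ...) {
  tibble::tibble(tree = seq_len(x$n_trees), d = x$per_tree %||% x$d)
}

#' @rdname tidy.phylo_d
#' @export
glance.phylo_d <- function(x, ...) {
  tibble::tibble(d = x$d, d_sd = x$d_sd, n_trees = x$n_trees, n_perm = x$n_perm)
}
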