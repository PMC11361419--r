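#' Configure a synthetic species pool
#'
#' The generator emulates the statistical structure the inference pipeline
#' assumes in real Red List work: 12 predictors (biological traits, human
#' uses) clustered within families, occurrence clouds whose spread controls
#' range size, a latent threat process that is logistic in range size, body
#' size and growth rate, a large data-deficient/not-evaluated (DDNE)
#' fraction masking the true status, and per-trait missingness.
#'
#' @param n_species Number of species to draw.
#' @param n_families Number of families; genera nest within families.
#' @param threat_model Named or positional numeric vector
#'   `(intercept, b_range, b_size, b_growth)`: coefficients of the logistic
#'   latent-threat model on standardized log range-scale, log maximum length
#'   and log growth rate. The defaults encode the canonical risk syndrome —
#'   small range, large body, slow growth (`b_range` < 0, `b_size` > 0,
#'   `b_growth` < 0).
#' @param ddne_fraction Fraction of species whose status is masked to DDNE.
#' @param missingness_rates Per-trait missingness proportions in \[0, 1\];
#'   a named vector over (a subset of) the 12 predictors, recycled scalar
#'   allowed.
#' @param occ_per_species Length-2 `(min, max)` counts of occurrence points
#'   per species; min must be at least 2.
#' @param missing_by_family If `TRUE`, missingness is concentrated in a
#'   random half of the families (taxonomically clustered gaps) instead of
#'   missing-completely-at-random.
#' @param seed Master seed for the pool.
#' @return A `species_config` list.
#' @export
species_config <- function(n_species,
                           n_families = max(3L, round(n_species / 12)),
                           threat_model = c(intercept = -1.5, b_range = -1.5,
                                            b_size = 0.8, b_growth = -0.8),
                           ddne_fraction = 0.38,
                           missingness_rates = 0.1,
                           occ_per_species = c(5L, 60L),
                           missing_by_family = FALSE,
                           seed = 1L) {
  if (n_species < 0) abort("`n_species` must be nonnegative.", class = "riskfill_config_error")
  if (ddne_fraction < 0 || ddne_fraction > 1) {
    abort("`ddne_fraction` must lie in [0, 1].", class = "riskfill_config_error")
  }
  if (any(missingness_rates < 0) || any(missingness_rates > 1)) {
    abort("`missingness_rates` must lie in [0, 1].", class = "riskfill_config_error")
  }
  if (length(occ_per_species) != 2 || occ_per_species[1] < 2 ||
      occ_per_species[1] > occ_per_species[2]) {
    abort("`occ_per_species` must be (min >= 2, max >= min).", class = "riskfill_config_error")
  }
  if (length(threat_model) != 4) {
    abort("`threat_model` needs 4 coefficients.", class = "riskfill_config_error")
  }
  structure(
    list(
      n_species = as.integer(n_species), n_families = as.integer(max(n_families, 1L)),
      threat_model = setNames(as.numeric(threat_model),
                              c("intercept", "b_range", "b_size", "b_growth")),
      ddne_fraction = ddne_fraction,
      missingness_rates = missingness_rates,
      occ_per_species = as.integer(occ_per_species),
      missing_by_family = isTRUE(missing_by_family),
      seed = as.integer(seed)
    ),
    class = "species_config"
  )
}

# The 12 predictor columns every downstream model consumes.
#' Names of the 12 predictor traits
#' @return Character vector of predictor column names.
#' @export
trait_names <- function() {
  c("growth_k", "max_length_cm", "trophic_level", "depth_min_m", "depth_max_m",
    "reproduction_mode", "fertilization", "body_shape", "climate_niche",
    "water_column", "price_category", "aquarium_interest")
}

trait_levels <- list(
  reproduction_mode = c("dioecism", "protandry", "protogyny", "hermaphrodite", "parthenogenesis"),
  fertilization     = c("external", "internal", "mouth", "brood_pouch", "other"),
  body_shape        = c("fusiform", "elongated", "compressed", "eel_like", "flat"),
  climate_niche     = c("tropical", "subtropical", "temperate", "polar"),
  water_column      = c("benthic", "demersal", "benthopelagic", "pelagic"),
  price_category    = c("low", "medium", "high", "very_high"),
  aquarium_interest = c("none", "minor", "commercial")
)

#' Sample a species pool in a world
#'
#' Generation proceeds in seeded stages (family effects, species traits,
#' ranges and occurrences, threat labels, status masking, missingness), each
#' with its own seed derived from the master seed in that order.
#'
#' Continuous traits are lognormal around family-level means, so trait
#' variance within families is smaller than between families. Occurrences
#' are drawn from a species-specific isotropic Gaussian kernel centred at a
#' random point of the grid; the kernel width sets range size and doubles as
#' the range-size covariate of the threat model. The true status is
#' Bernoulli with logit linear in standardized log kernel area, log maximum
#' length and log growth rate; `observed_status` masks a `ddne_fraction`
#' random subset of species to `"DDNE"`.
#'
#' @param world A [build_world()] result.
#' @param config A [species_config()].
#' @return A `species_pool`: list of two tibbles, `species` (one row per
#'   species: taxonomy, 12 predictors, `range_scale_km`, `true_status`,
#'   `observed_status`) and `occurrences` (`species_id`, `x`, `y` in km).
#' @examples
#' w <- build_world(world_config(30, 30, seed = 1))
#' pool <- sample_species(w, species_config(n_species = 50, seed = 2))
#' dplyr::count(pool$species, observed_status)
#' @export
sample_species <- function(world, config) {
  stopifnot(inherits(world, "riskfill_world"), inherits(config, "species_config"))
  n <- config$n_species
  if (n == 0L) {
    return(new_species_pool(empty_species_tbl(), tibble::tibble(
      species_id = character(), x = numeric(), y = numeric()
    ), config))
  }
  seeds <- derive_seeds(config$seed, 6)
  grid <- world$grid
  ext_x <- grid$cols * grid$cell_km
  ext_y <- grid$rows * grid$cell_km

  # stage 1: family-level effects -------------------------------------------
  set.seed(seeds[1])
  nf <- config$n_families
  fam <- tibble::tibble(
    family = sprintf("Fam%03d", seq_len(nf)),
    n_genera = pmax(1L, stats::rpois(nf, 2)),
    mu_growth = rnorm(nf, log(0.3), 0.6),
    mu_length = rnorm(nf, log(40), 0.8),
    mu_trophic = rnorm(nf, 3.2, 0.45),
    mu_dmin = rnorm(nf, log(10), 0.9),
    mu_dspan = rnorm(nf, log(150), 0.7),
    mu_scale = rnorm(nf, log(0.06 * min(ext_x, ext_y)), 0.6)
  )
  fam_pref <- purrr::map(trait_levels, function(lv) sample(lv, nf, replace = TRUE))

  # stage 2: species traits --------------------------------------------------
  set.seed(seeds[2])
  fidx <- sample.int(nf, n, replace = TRUE)
  genus_no <- vapply(fidx, function(i) sample.int(fam$n_genera[i], 1L), integer(1))
  species <- tibble::tibble(
    species_id = sprintf("sp%05d", seq_len(n)),
    family = fam$family[fidx],
    genus = sprintf("%s_g%d", fam$family[fidx], genus_no),
    growth_k = exp(fam$mu_growth[fidx] + rnorm(n, 0, 0.25)),
    max_length_cm = exp(fam$mu_length[fidx] + rnorm(n, 0, 0.3)),
    trophic_level = pmin(pmax(fam$mu_trophic[fidx] + rnorm(n, 0, 0.2), 2), 4.8),
    depth_min_m = exp(fam$mu_dmin[fidx] + rnorm(n, 0, 0.3)) - 1
  )
  species$depth_min_m <- pmin(pmax(species$depth_min_m, 0), world$config$depth_range_m[2] * 0.8)
  span <- exp(fam$mu_dspan[fidx] + rnorm(n, 0, 0.3))
  species$depth_max_m <- pmin(species$depth_min_m + span, world$config$depth_range_m[2])
  for (tr in names(trait_levels)) {
    lv <- trait_levels[[tr]]
    pref <- fam_pref[[tr]][fidx]
    pick <- ifelse(runif(n) < 0.6, pref, lv[sample.int(length(lv), n, replace = TRUE)])
    species[[tr]] <- factor(pick, levels = lv)
  }
  species$range_scale_km <- exp(fam$mu_scale[fidx] + rnorm(n, 0, 0.35))
  species$range_scale_km <- pmin(species$range_scale_km, 0.5 * min(ext_x, ext_y))

  # stage 3: occurrences ------------------------------------------------------
  set.seed(seeds[3])
  n_occ <- sample(seq(config$occ_per_species[1], config$occ_per_species[2]), n, replace = TRUE)
  cx <- runif(n, 0, ext_x); cy <- runif(n, 0, ext_y)
  occ <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      species_id = species$species_id[i],
      x = pmin(pmax(rnorm(n_occ[i], cx[i], species$range_scale_km[i]), 0), ext_x),
      y = pmin(pmax(rnorm(n_occ[i], cy[i], species$range_scale_km[i]), 0), ext_y)
    )
  })

  # stage 4: latent threat process --------------------------------------------
  set.seed(seeds[4])
  z <- function(v) as.numeric(scale(v))
  b <- config$threat_model
  eta <- b["intercept"] +
    b["b_range"] * z(log(pi * species$range_scale_km^2)) +
    b["b_size"] * z(log(species$max_length_cm)) +
    b["b_growth"] * z(log(species$growth_k))
  species$p_threat <- plogis(eta)
  species$true_status <- ifelse(rbinom(n, 1, species$p_threat) == 1,
                                "Threatened", "NonThreatened")

  # stage 5: status masking ----------------------------------------------------
  set.seed(seeds[5])
  ddne <- runif(n) < config$ddne_fraction
  species$observed_status <- ifelse(ddne, "DDNE", species$true_status)

  # stage 6: missingness -------------------------------------------------------
  set.seed(seeds[6])
  rates <- config$missingness_rates
  if (is.null(names(rates))) {
    rates <- setNames(rep_len(rates, length(trait_names())), trait_names())
  }
  if (config$missing_by_family) {
    gap_fams <- sample(fam$family, ceiling(nf / 2))
    fam_boost <- ifelse(species$family %in% gap_fams, 2, 0.25)
  } else {
    fam_boost <- rep(1, n)
  }
  for (tr in intersect(names(rates), trait_names())) {
    miss <- runif(n) < pmin(rates[[tr]] * fam_boost, 1)
    species[[tr]][miss] <- NA
  }

  new_species_pool(species, occ, config)
}

empty_species_tbl <- function() {
  tb <- tibble::tibble(
    species_id = character(), family = character(), genus = character(),
    growth_k = numeric(), max_length_cm = numeric(), trophic_level = numeric(),
    depth_min_m = numeric(), depth_max_m = numeric()
  )
  for (tr in names(trait_levels)) tb[[tr]] <- factor(character(), levels = trait_levels[[tr]])
  tb$range_scale_km <- numeric(); tb$p_threat <- numeric()
  tb$true_status <- character(); tb$observed_status <- character()
  tb
}

new_species_pool <- function(species, occurrences, config) {
  structure(list(species = species, occurrences = occurrences, config = config),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("<species_pool> %d species, %d occurrences\n",
              nrow(x$species), nrow(x$occurrences)))
  if (nrow(x$species)) {
    print(dplyr::count(x$species, .data$observed_status))
  }
  invisible(x)
}

#' Write / read a species pool as plain CSV
#'
#' Two files are written: `species.csv` (one row per species) and
#' `occurrences.csv` (`species_id`, `x`, `y`).
#'
#' @param pool A `species_pool`.
#' @param dir Directory (created if needed).
#' @return `write_species_pool()` returns `dir` invisibly;
#'   `read_species_pool()` returns a `species_pool` (without generator
#'   config).
#' @export
write_species_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "species_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(pool$species, file.path(dir, "species.csv"))
  readr::write_csv(pool$occurrences, file.path(dir, "occurrences.csv"))
  invisible(dir)
}

#' @rdname write_species_pool
#' @export
read_species_pool <- function(dir) {
  sp <- readr::read_csv(file.path(dir, "species.csv"), show_col_types = FALSE)
  for (tr in names(trait_levels)) {
    if (tr %in% names(sp)) sp[[tr]] <- factor(sp[[tr]], levels = trait_levels[[tr]])
  }
  occ <- readr::read_csv(file.path(dir, "occurrences.csv"), show_col_types = FALSE)
  new_species_pool(sp, occ, NULL)
}
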