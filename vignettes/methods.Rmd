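---
title: "Gap-filling extinction-risk status: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-filling extinction-risk status: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskfill)
library(dplyr)
```

## The problem

Most marine teleost fishes have never been assessed against the Red List
criteria: they are Data Deficient or Not Evaluated (together, "DDNE").
Conservation planning that ranks sites by the extinction risk of the
species they hold is therefore built on a labels table with a very large
hole in it. `riskfill` implements an in-silico route around that hole:

1. build per-species range maps from occurrence points,
2. complete the trait table with a performance-gated imputer,
3. train balanced down-sampled ensembles of two learner families on the
   assessed species and let their models vote on the DDNE species,
4. merge the two algorithms' consensus calls into a final status,
5. quantify how statuses cluster on a phylogeny (the D statistic),
6. run a gap analysis against the protected-area network, and
7. re-rank unprotected cells with a greedy removal algorithm under
   status-based species weights, before vs. after gap-filling.

Every stage runs on a synthetic world, so the whole pipeline is testable
end to end without any data download. The synthetic generator is
first-class, seeded code, not a fixture: its defaults encode the
assumptions the inference stages rely on.

## The synthetic world and species pool

`build_world()` creates an abstract equal-area grid of `cell_km`-sided
square cells (default 10 km, hence 100 km² cells — areal accounting is
exact by construction, e.g. 149 cells ↔ 14,900 km²). Two layers ride on
the grid: a per-cell maximal depth (a smooth basin gradient with lognormal
roughness, scaled into `depth_range_m`) and a Bernoulli protected-area
mask with success probability `pa_fraction`. Real protected areas are
spatially clumped; the independent-Bernoulli mask is deliberately the
simplest null layer that exercises coverage and masking logic, and tests
on it say nothing about spatial autocorrelation effects.

`sample_species()` draws a pool with the statistical structure the
pipeline assumes:

* **Taxonomic clustering of traits.** Continuous traits are lognormal
  around family-level means (family SD larger than species SD), so
  within-family variance is smaller than between-family variance;
  categorical traits follow a family-preferred level with probability
  0.6. This is what makes `genus`/`family` informative model features,
  as they are in practice.
* **Range construction.** Occurrences (between `occ_per_species` bounds,
  minimum 2) come from an isotropic Gaussian kernel at a random centre;
  the kernel width `range_scale_km` controls realized range size.
* **Latent threat process.** The probability of being truly Threatened is
  logistic with linear predictor
  `intercept + b_range·z(log kernel area) + b_size·z(log max length) + b_growth·z(log growth K)`.
  The default coefficients `(-1.5, -1.5, 0.8, -0.8)` encode the canonical
  risk syndrome — small range, large body, slow growth — with a realized
  Threatened prevalence of roughly 15–20%, i.e. a strongly imbalanced
  pool, which is the regime the down-sampling ensemble exists for.
* **Masking and missingness.** A `ddne_fraction` (default 0.38, the
  observed DDNE share among marine teleosts) of species have their status
  masked to DDNE; trait values go missing completely at random per trait
  (`missingness_rates`), with an optional family-clustered variant
  (`missing_by_family`) because real trait gaps track taxonomy.

All randomness flows from one master seed, split per stage in a fixed
documented order (family effects, traits, occurrences, threat, masking,
missingness), so a stage can be reasoned about in isolation and identical
configurations are bit-reproducible.

Because real-world distributional evidence for each trait is thin, these
defaults are *fixtures*, not estimates: passing tests show the
pipeline's logic is correct under a plausible data-generating process,
not that any particular ocean looks like this.

## Range building

A species' range is the convex polygon around its occurrences, split into
four independent hulls by a vertical and a horizontal line (defaults: the
grid midlines — the synthetic analogue of splitting at the equator and an
ocean-basin meridian so that a bi-hemispheric species is not bridged by
one global hull). Quadrants with fewer than three non-collinear points get
a minimal polygon by buffering each point into a half-cell square; species
with fewer than two distinct points are flagged unbuildable.

Rasterization uses a boundary-inclusive centre test: a cell is in the
range iff its centre lies inside or on any polygon, implemented as an
exact half-plane test for convex polygons. Centre inclusion was chosen
over area-overlap rules because it is deterministic, cheap, and trivially
checked against an independent point-in-polygon oracle cell by cell. The
two-step aggregation used with real data (coarse grid, then 10 km
equal-area grid) is collapsed into direct rasterization on the target
grid; synthetic coordinates are already planar and equal-area, so nothing
is lost. Built ranges additionally include the cell under every
occurrence point, so no observation is dropped before depth refinement.

`depth_refine()` removes cells whose maximal depth falls outside the
species' known depth interval. It can only shrink ranges; a missing bound
is unconstrained; species emptied by refinement are flagged rather than
silently dropped. No minimum range size is enforced — the 149-cell
minimum seen in real data is an observed fact, not a floor.

## Gated trait imputation

The imputer is the iterative tree-ensemble scheme familiar from
missForest-style workflows, authored here: initialize gaps with the column
mean/mode, then sweep the columns in order of increasing missingness,
refitting a random forest per target and re-predicting its missing
entries, until the relative change between sweeps drops below `1e-3` or
10 sweeps have run. The imputation forests use `mtry = ceiling(2p/3)`
rather than the ranger default `sqrt(p)`: with only a dozen candidate
covariates, `sqrt(p)` too often excludes the one informative predictor
from a split, which measurably degrades the recovery of deterministic
relations between traits.

Whether a trait may be imputed at all is decided by holdout evaluation
(`evaluate_imputer()`): complete cases are split 80/20, the trait is
masked on the test fifth, the imputer runs, and the masked entries are
scored — R² for numeric traits, accuracy for categorical ones. The gate
is **strict**: a trait is imputed only if its performance *exceeds* 0.6; a
trait at exactly 0.6 keeps its gaps. Species with more than
`max_missing_fields` missing predictors (default 6 of 12 — the cap is a
configuration knob, since "too many" is not defined more precisely
anywhere) are excluded *before* imputation and flagged unpredictable;
exclusion-first keeps the imputer's training pool honest. Observed values
are never altered, and the imputation is single-shot: no multiple
imputation or uncertainty propagation, matching the workflow this package
reimplements.

## Balanced down-sampled ensembles and consensus

With ~25 assessed Non-Threatened species for every assessed Threatened
one, a single model would learn the base rate. Instead
`make_balanced_subsets()` builds `B` (default 24) balanced subsets: all
Threatened species plus an equal-size Non-Threatened draw. Draws maximize
coverage before reuse — a shuffled queue of Non-Threatened ids is consumed
block by block and only reshuffled when exhausted — so when
`n_NT = B·n_T` the draws partition the majority class exactly.

Each subset is fitted under `k`-fold (default 10) class-stratified
cross-validation, giving `B·k` models (240 at the defaults). Held-out
performance is tallied three ways, summing to 100% of held-out cases:
true predictions (either class correct), false positives (Non-Threatened
called Threatened), false negatives (Threatened called Non-Threatened).

Two learner families are provided. The tree ensemble is a 500-tree
probability forest; no class weights are needed because balance is
guaranteed by construction. The network learner is a single-hidden-layer
perceptron (`nnet`), width 32, logistic activations, weight decay 0.01,
on standardized one-hot features — the classical shallow network of the R
modelling stack; weight decay plays the regularizing role that early
stopping would in a deep-learning framework. Model features are the 12
traits, the occurrence-derived range size, and genus and family as
categorical predictors; range size matters because geographic range is
the strongest single correlate of extinction risk, and a status model
blind to it cannot recover a range-driven threat process.

All `B·k` models vote on every unassessed species; `p` is the fraction of
votes for Threatened. The consensus rule is strict: Threatened iff
`p > τ` (default 0.8), Non-Threatened iff `1 − p > τ`, otherwise no call
— `p` exactly at the threshold abstains. Counting all fold models as
voters (rather than one refit per subset) uses the ensemble the
cross-validation already paid for; the alternative changes only the
denominator of `p`.

## Merging the two algorithms

`merge_calls()` implements the complementary three-branch rule: both
agree → assign; exactly one made a call → assign it; conflict → stay
DDNE. Two abstentions also stay DDNE — the only reading consistent with
the branch table. The strict variant assigns only on agreement. Both
rules are symmetric, and strict assignments are provably a subset of
complementary ones. Assessed species never change status.
`transition_summary()` tallies counts per category before and after and
derives percent changes (`100·(after−before)/before`) and pool shares;
when given bare printed tallies rather than species tables it does not
insist the two totals match, because published accountings of "before"
and "after" sometimes draw the line around slightly different pools.

## Phylogenetic signal of a binary status

The D statistic contrasts the observed sum of sister-clade differences of
a binary trait with two nulls: tip-label permutation (random placement,
D = 1 in expectation) and Brownian motion thresholded to the observed
prevalence (clumped placement, D = 0):

D = (d_obs − mean d_Brownian) / (mean d_random − mean d_Brownian).

Node values are daughter means accumulated postorder; polytomies are
resolved to binary first. The Brownian threshold is set to match the
observed number of 1-tips, and the null averages the two threshold
directions (top-n₁ and bottom-n₁ tips as the "1" class) — an unbiased
symmetrization that makes D exactly invariant to swapping the 0/1 coding,
not merely invariant in expectation. With a list of trees D is reported
per tree and as mean ± SD, which is how multi-tree posterior samples are
normally summarized. Constant traits raise an error: D is undefined.

## Gap analysis

Conservation targets are log-linear in range size between two anchors:
100% of range protected at or below 10,000 km², 10% at or above
390,000 km², linear in log₁₀(range km²) between (the base of the
logarithm is immaterial for a line through two fixed points; base 10 is
used for reproducibility). The function is continuous, nonincreasing and
clamped — e.g. the geometric mean of the anchors maps to exactly 55%.
Coverage is the percentage of range cells inside the protected mask;
achievement is `100·coverage/target`, capped at 100 with the uncapped
value retained for audit (whether over-achievers should be capped is not
specified anywhere authoritative; capping keeps the group comparisons from
being driven by a few tiny well-covered ranges). Group comparisons use
the standard rank machinery: Kruskal–Wallis across three or more status
groups, Wilcoxon rank-sum for pairs.

## Greedy prioritization ranking

`zonation_rank()` iteratively removes the lowest-valued unprotected cells
and ranks them by removal order, normalized to [0, 1] (last removed = 1 =
highest priority). The cell value is `Σⱼ wⱼ·q_ij` in the default
`additive` mode, where `q_ij` is cell *i*'s fraction of species *j*'s
*remaining* unprotected distribution, recomputed after every iteration —
so a species' surviving cells gain value as its range erodes. A
`max_benefit` mode (the core-area flavour, `maxⱼ wⱼ·q_ij`) is also
implemented: the published description of the procedure names the
core-area rule but verbally states the additive one, and the text cannot
resolve which was actually run, so both exist and the stated rule is the
default. Design points, all test-fixed:

* ties break deterministically by lowest cell index;
* `warp` cells are removed per iteration in one block without intra-block
  recomputation (default 1 for toys; 1,000 is the global-scale setting);
* protected cells are never ranked and by default excluded from `q`
  denominators (a flag includes them);
* multiplying all weights by a constant cannot change the ranking.

Weights default to 1 (Non-Threatened), 2 (DDNE), 6 (Threatened). The
sensitivity scheme downweights model-predicted statuses: assessed species
keep the fixed weights; predicted Threatened get `2 + p` rescaled onto
[2, 5] and predicted Non-Threatened `2 − p` rescaled onto [1, 2], with
DDNE at 2. Since admissible `p` lies in `(τ, 1]`, "rescaled" is read as
the affine map of that interval onto the stated one — the reading that
hits both published endpoints; rescaling `p` before the additive form
gives the same endpoints and differs only in slope, and the choice is
confined to one helper.

`delta_rank()` differences two scenarios cell by cell (after − before);
it requires identical grids and protected masks and is antisymmetric
under swapping scenarios.

## Numerical and testing choices

* Boundary-inclusive geometry throughout (hull membership, rasterization)
  with a relative tolerance of 1e-9 of the polygon extent.
* The greedy ranking is verified against an exhaustive oracle that
  recomputes every cell value from scratch each step, over randomized
  instances on grids up to 4×4 with up to 3 species, in both value modes.
* Rasterization is verified cell-for-cell against an independent
  point-in-polygon routine (`mgcv::in.out`) on randomized convex polygons
  over grids up to 20×20; knife-edge boundary cases are kept out of the
  randomized comparison and pinned by constructed rectangle fixtures
  instead.
* D-statistic calibration uses 50 random 64-tip trees with 100 null
  replicates each; label recovery uses 5 independent worlds of 700
  species with 24×10 forest ensembles of 200 trees; the imputer noise
  floor averages 10 seeds. These sizes keep the full suite under a few
  minutes while leaving the stochastic bands (±0.15 on D; ≥0.8 agreement)
  comfortably resolvable.
* Test fixtures fix their seeds. For the partial-dependence monotonicity
  check the fixture seed matters beyond reproducibility: a Bernoulli
  label draw can contain genuine local prevalence inversions that any
  well-fit forest will reproduce, so per-step monotonicity within a small
  tolerance is a property of a realization, not of every realization.

## Known limitations

* The synthetic occurrence process has no sampling-effort gradient, no
  coastline geometry and no spatial bias; conclusions about robustness to
  real survey bias cannot be drawn from these tests.
* The protected-area mask is spatially independent Bernoulli; clumped
  protection interacts with range geometry in ways the tests do not
  exercise.
* Statuses are binary (plus DDNE); the finer Red List categories are
  deliberately out of scope, as is probability calibration of the vote
  fractions and any hyperparameter search.
* The network learner is a shallow logistic-activation perceptron; it is
  a faithful stand-in for "a second, differently-biased learner family",
  not a deep-learning replica.

## A worked toy run

```{r example, eval = FALSE}
w <- build_world(world_config(40, 40, pa_fraction = 0.2, seed = 11))
pool <- sample_species(w, species_config(n_species = 300, seed = 7))
ranges <- build_ranges(pool, w) |> depth_refine(w, pool$species)

rep <- evaluate_imputer(pool$species, seed = 3)
imp <- impute_traits(pool$species, rep, seed = 3)

sizes <- range_sizes(ranges)
tbl <- dplyr::left_join(imp$table, sizes, by = "species_id")
labeled <- dplyr::filter(tbl, observed_status != "DDNE") |>
  dplyr::mutate(status = observed_status)
ddne <- dplyr::filter(tbl, observed_status == "DDNE")

fit_rf <- fit_status_ensemble(labeled, config = ensemble_config(algorithm = "rf", seed = 5))
fit_ann <- fit_status_ensemble(labeled, config = ensemble_config(algorithm = "ann", seed = 5))
fin <- finalize_status(
  dplyr::transmute(pool$species, species_id, status = observed_status),
  consensus_predict(fit_rf, ddne), consensus_predict(fit_ann, ddne),
  unpredictable = imp$excluded
)
transition_summary(fin, fin)   # picks status_before / status_after

after <- dplyr::transmute(fin, species_id, status = status_after)
autoplot(delta_rank(
  zonation_rank(ranges, assign_weights(dplyr::transmute(fin, species_id, status = status_before)), w),
  zonation_rank(ranges, assign_weights(after), w)
))
```
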