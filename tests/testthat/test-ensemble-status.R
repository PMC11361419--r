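test_that("balanced subsets hold all minority species plus equal-size draws", {
  set.seed(1)
  labeled <- tibble::tibble(
    species_id = sprintf("s%04d", 1:360),
    status = rep(c("Threatened", "NonThreatened"), c(30, 330))
  )
  subs <- make_balanced_subsets(labeled, n_subsets = 5, seed = 2)
  for (b in 1:5) {
    sb <- subs[subs$subset == b, ]
    expect_equal(sum(sb$status == "Threatened"), 30)
    expect_equal(sum(sb$status == "NonThreatened"), 30)
    expect_false(anyDuplicated(sb$species_id) > 0)
  }
  expect_error(
    make_balanced_subsets(tibble::tibble(species_id = c("a", "b"),
                                         status = c("Threatened", "Threatened")),
                          2),
    class = "riskfill_balance_error"
  )
})

test_that("with n_NT = B * n_T the majority draws form an exact partition", {
  labeled <- tibble::tibble(
    species_id = sprintf("s%04d", 1:(20 + 6 * 20)),
    status = rep(c("Threatened", "NonThreatened"), c(20, 120))
  )
  subs <- make_balanced_subsets(labeled, n_subsets = 6, seed = 3)
  nt_draws <- subs$species_id[subs$status == "NonThreatened"]
  counts <- table(nt_draws)
  expect_equal(length(counts), 120)          # every NT species used
  expect_true(all(counts == 1))              # exactly once
})

test_that("the ensemble holds exactly B * k models and is order-invariant", {
  pool <- separable_pool(n = 120, seed = 4)
  cfg <- ensemble_config(n_subsets = 3, cv_folds = 4, algorithm = "rf",
                         num_trees = 50, seed = 5)
  fit <- fit_status_ensemble(pool, features = c("range_size", "noise1"),
                             config = cfg)
  expect_equal(fit$n_models, 12)
  expect_equal(nrow(tidy(fit)), 12)

  newdata <- separable_pool(n = 40, seed = 6)
  v1 <- consensus_predict(fit, newdata)
  fit_rev <- fit
  fit_rev$models <- rev(fit$models)
  v2 <- consensus_predict(fit_rev, newdata)
  expect_equal(v1$call, v2$call)
  expect_equal(v1$p, v2$p)
  expect_error(fit_status_ensemble(pool, features = c("range_size"),
                                   config = ensemble_config(2, 70)),
               class = "riskfill_fold_error")
})

test_that("a deterministic threshold on one feature is learned almost perfectly", {
  accs <- vapply(1:5, function(s) {
    pool <- separable_pool(n = 200, seed = s)
    cfg <- ensemble_config(n_subsets = 2, cv_folds = 5, algorithm = "rf",
                           num_trees = 100, seed = s + 50)
    fit <- fit_status_ensemble(
      pool, features = c("range_size", "noise1", "noise2", "noise_f"),
      config = cfg)
    glance(fit)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("consensus calls follow the strict > tau rule", {
  # direct fraction arithmetic on synthetic vote counts
  fake_votes <- function(votes_t, total, tau = 0.8) {
    p <- votes_t / total
    dplyr::case_when(p > tau ~ "Threatened",
                     (1 - p) > tau ~ "NonThreatened",
                     .default = "NoCall")
  }
  expect_equal(fake_votes(240, 240), "Threatened")        # p = 1
  expect_equal(fake_votes(192, 240), "NoCall")            # p = 0.8 exactly
  expect_equal(fake_votes(200, 240), "Threatened")        # p = 0.8333
  expect_equal(fake_votes(40, 240), "NonThreatened")      # 1 - p = 0.8333

  # and the implementation agrees on a fitted ensemble
  pool <- separable_pool(n = 150, seed = 9)
  cfg <- ensemble_config(n_subsets = 2, cv_folds = 3, algorithm = "rf",
                         num_trees = 60, seed = 10)
  fit <- fit_status_ensemble(pool, features = c("range_size", "noise1"),
                             config = cfg)
  nd <- separable_pool(n = 30, seed = 11)
  v <- consensus_predict(fit, nd)
  expect_true(all(v$votes_total == 6))
  manual <- fake_votes(v$votes_threatened, v$votes_total)
  expect_equal(v$call, manual)
  expect_true(all(v$p >= 0 & v$p <= 1))
})

test_that("species with missing features are returned as NoCall with a reason", {
  pool <- separable_pool(n = 100, seed = 12)
  cfg <- ensemble_config(n_subsets = 1, cv_folds = 2, algorithm = "rf",
                         num_trees = 40, seed = 13)
  fit <- fit_status_ensemble(pool, features = c("range_size", "noise1"),
                             config = cfg)
  nd <- separable_pool(n = 10, seed = 14)
  nd$range_size[3] <- NA
  v <- consensus_predict(fit, nd)
  expect_equal(v$call[3], "NoCall")
  expect_equal(v$reason[3], "missing_features")
  expect_equal(v$votes_total[3], 0L)
})

test_that("the network learner fits and votes on the same schema", {
  pool <- separable_pool(n = 150, seed = 15)
  cfg <- ensemble_config(n_subsets = 2, cv_folds = 2, algorithm = "ann",
                         hidden_units = 8, maxit = 80, seed = 16)
  fit <- fit_status_ensemble(
    pool, features = c("range_size", "noise1", "noise_f"), config = cfg)
  expect_equal(fit$n_models, 4)
  expect_gte(glance(fit)$accuracy, 0.8)      # separable signal
  v <- consensus_predict(fit, separable_pool(n = 25, seed = 17))
  expect_true(all(v$call %in% c("Threatened", "NonThreatened", "NoCall")))
})

test_that("label-shuffled pools produce chance accuracy and inflated NoCall", {
  set.seed(18)
  accs <- c(); nocall_shuffled <- c(); nocall_signal <- c()
  for (s in 1:2) {
    pool <- separable_pool(n = 240, seed = 20 + s)
    cfg <- ensemble_config(n_subsets = 6, cv_folds = 5, algorithm = "rf",
                           num_trees = 60, seed = 30 + s)
    feats <- c("range_size", "noise1", "noise2")
    nd <- separable_pool(n = 60, seed = 40 + s)

    fit_sig <- fit_status_ensemble(pool, features = feats, config = cfg)
    nocall_signal <- c(nocall_signal,
                       mean(consensus_predict(fit_sig, nd)$call == "NoCall"))

    pool$status <- sample(pool$status)       # destroy the signal
    fit <- fit_status_ensemble(pool, features = feats, config = cfg)
    accs <- c(accs, tidy(fit)$accuracy)
    nocall_shuffled <- c(nocall_shuffled,
                         mean(consensus_predict(fit, nd)$call == "NoCall"))
  }
  # held-out accuracy collapses to chance on balanced folds
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  # consensus abstains far more often than under a real signal
  expect_gt(mean(nocall_shuffled), mean(nocall_signal) + 0.2)
  expect_gt(mean(nocall_shuffled), 0.3)
})
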