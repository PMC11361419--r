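#' Configure a balanced down-sampled status ensemble
#'
#' The labeled pool is highly imbalanced (few Threatened, many
#' Non-Threatened), so training proceeds on `n_subsets` balanced
#' down-samples: every subset holds all Threatened species plus an
#' equal-size draw of Non-Threatened species. Each subset is fitted under
#' `cv_folds`-fold cross-validation, giving `n_subsets * cv_folds` models
#' whose votes over unlabeled species feed a strict consensus rule.
#'
#' @param n_subsets Number of balanced down-samples B (default 24).
#' @param cv_folds Folds k per subset (default 10) — 240 models at the
#'   defaults.
#' @param consensus_threshold Consensus fraction tau in (0.5, 1\]; a status
#'   is attributed only when strictly more than `tau` of the models agree
#'   (default 0.8).
#' @param algorithm `"rf"` (random forest) or `"ann"` (single-hidden-layer
#'   neural network).
#' @param num_trees Trees per forest (`"rf"`).
#' @param hidden_units,decay,maxit Network hyperparameters (`"ann"`).
#' @param seed Master seed; one seed per (subset, fold) model is derived.
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(n_subsets = 24, cv_folds = 10,
                            consensus_threshold = 0.8,
                            algorithm = c("rf", "ann"),
                            num_trees = 500, hidden_units = 32,
                            decay = 0.01, maxit = 150, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (n_subsets < 1) abort("`n_subsets` must be >= 1.", class = "riskfill_config_error")
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.", class = "riskfill_config_error")
  if (consensus_threshold <= 0.5 || consensus_threshold > 1) {
    abort("`consensus_threshold` must lie in (0.5, 1].", class = "riskfill_config_error")
  }
  structure(
    list(n_subsets = as.integer(n_subsets), cv_folds = as.integer(cv_folds),
         consensus_threshold = consensus_threshold, algorithm = algorithm,
         num_trees = num_trees, hidden_units = hidden_units, decay = decay,
         maxit = maxit, seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Balanced down-sampled training subsets
#'
#' Each subset takes all Threatened species plus a same-size sample of
#' Non-Threatened species. Non-Threatened draws maximize coverage before
#' reuse: a shuffled queue of Non-Threatened ids is consumed block by block
#' and reshuffled only when exhausted, so with `n_NT = B * n_T` the samples
#' form an exact partition.
#'
#' @param labeled Tibble with `species_id` and `status` in
#'   `c("Threatened", "NonThreatened")`.
#' @param n_subsets Number of subsets B.
#' @param seed Seed for the shuffles.
#' @return Tibble `subset` (1..B), `species_id`, `status`.
#' @export
make_balanced_subsets <- function(labeled, n_subsets, seed = 1L) {
  t_ids <- labeled$species_id[labeled$status == "Threatened"]
  nt_ids <- labeled$species_id[labeled$status == "NonThreatened"]
  if (length(t_ids) < 1) abort("No Threatened species to balance on.", class = "riskfill_balance_error")
  if (length(nt_ids) < length(t_ids)) {
    abort("Fewer Non-Threatened than Threatened species; cannot down-sample.",
          class = "riskfill_balance_error")
  }
  n_t <- length(t_ids)
  set.seed(seed)
  queue <- sample(nt_ids)
  draws <- vector("list", n_subsets)
  for (b in seq_len(n_subsets)) {
    if (length(queue) < n_t) {
      # top up from a fresh shuffle, avoiding duplicates within the block
      top <- sample(setdiff(nt_ids, queue))
      queue <- c(queue, top)
    }
    draws[[b]] <- queue[seq_len(n_t)]
    queue <- queue[-seq_len(n_t)]
  }
  purrr::map_dfr(seq_len(n_subsets), function(b) {
    tibble::tibble(
      subset = b,
      species_id = c(t_ids, draws[[b]]),
      status = rep(c("Threatened", "NonThreatened"), each = n_t)
    )
  })
}

# --- feature handling -------------------------------------------------------

# Freeze the feature schema (predictor names + factor levels) from the full
# table so every model, and later prediction, sees identical encodings.
feature_schema <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    abort(paste0("Unknown feature(s): ", paste(missing, collapse = ", ")),
          class = "riskfill_schema_error")
  }
  lv <- lapply(table[features], function(col) {
    if (is.numeric(col)) NULL else sort(unique(as.character(stats::na.omit(col))))
  })
  list(features = features, levels = lv)
}

encode_features <- function(table, schema) {
  df <- as.data.frame(table)[schema$features]
  for (f in schema$features) {
    if (!is.null(schema$levels[[f]])) {
      df[[f]] <- factor(as.character(df[[f]]), levels = schema$levels[[f]])
    }
  }
  df
}

# one-hot numeric matrix for the network learner
one_hot <- function(df) {
  mm <- stats::model.matrix(~ . - 1, data = df,
                            contrasts.arg = lapply(
                              df[vapply(df, is.factor, logical(1))],
                              stats::contrasts, contrasts = FALSE))
  scale_info <- list(center = apply(mm, 2, mean), scale = apply(mm, 2, sd))
  scale_info$scale[scale_info$scale == 0] <- 1
  list(x = scale(mm, scale_info$center, scale_info$scale), info = scale_info)
}

# --- fitting ----------------------------------------------------------------

#' Fit a balanced down-sampled status ensemble
#'
#' Splits each balanced subset into `cv_folds` class-stratified folds, fits
#' one model per (subset, fold) on the other folds — `B * k` models in all —
#' and evaluates each on its held-out fold. The held-out tallies follow the
#' three-way accounting used for status models: true predictions (either
#' class correct), false positives (Non-Threatened called Threatened) and
#' false negatives (Threatened called Non-Threatened), which sum to 100% of
#' held-out cases.
#'
#' @param labeled Tibble with `species_id`, `status` and the feature columns
#'   (complete cases only are used).
#' @param features Feature column names (default: the 12 traits, the
#'   occurrence-derived range size (`area_km2` or the generator's
#'   `range_scale_km`) and `genus`/`family`, where present — status models
#'   are trained on occurrences as well as traits, taxonomy and uses).
#' @param config An [ensemble_config()].
#' @return A `status_ensemble` object: fitted models, per-model held-out
#'   metrics (see [tidy.status_ensemble()]), the frozen feature schema and
#'   the config.
#' @export
fit_status_ensemble <- function(labeled, features = NULL, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  features <- features %||%
    intersect(c(trait_names(), "area_km2", "range_scale_km", "genus", "family"),
              names(labeled))
  schema <- feature_schema(labeled, features)
  keep <- stats::complete.cases(as.data.frame(labeled)[features])
  n_dropped <- sum(!keep)
  if (n_dropped > 0.2 * length(keep)) {
    warn(sprintf(
      "%d of %d labeled species dropped for missing features; consider restricting `features` to gated/complete traits.",
      n_dropped, length(keep)))
  }
  labeled <- labeled[keep, , drop = FALSE]
  subsets <- make_balanced_subsets(labeled[, c("species_id", "status")],
                                   config$n_subsets, seed = config$seed)
  B <- config$n_subsets; k <- config$cv_folds
  seeds <- matrix(derive_seeds(config$seed + 1L, B * k), B, k)

  x_all <- encode_features(labeled, schema)
  y_all <- factor(labeled$status, levels = c("NonThreatened", "Threatened"))
  names(y_all) <- labeled$species_id
  rownames(x_all) <- labeled$species_id

  models <- list(); metrics <- list()
  for (b in seq_len(B)) {
    ids <- subsets$species_id[subsets$subset == b]
    y <- y_all[ids]
    n_class <- min(table(y))
    if (k > n_class) {
      abort(sprintf("cv_folds = %d exceeds the smallest class size %d in subset %d.",
                    k, n_class, b), class = "riskfill_fold_error")
    }
    set.seed(seeds[b, 1])
    fold <- integer(length(ids))
    for (cl in levels(y)) {                   # stratified fold assignment
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    for (f in seq_len(k)) {
      tr_ids <- ids[fold != f]; te_ids <- ids[fold == f]
      m <- fit_one_model(x_all[tr_ids, , drop = FALSE], y_all[tr_ids],
                         config, seed = seeds[b, f])
      pred <- predict_one_model(m, x_all[te_ids, , drop = FALSE])
      truth <- y_all[te_ids]
      n_te <- length(te_ids)
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        subset = b, fold = f,
        accuracy = mean(pred == truth),
        tp_rate = 100 * mean(pred == truth),
        fp_rate = 100 * sum(truth == "NonThreatened" & pred == "Threatened") / n_te,
        fn_rate = 100 * sum(truth == "Threatened" & pred == "NonThreatened") / n_te
      )
      models[[length(models) + 1L]] <- m
    }
  }
  structure(
    list(models = models, metrics = dplyr::bind_rows(metrics),
         schema = schema, config = config, n_models = length(models),
         n_train = sum(keep), n_dropped = n_dropped),
    class = "status_ensemble"
  )
}

fit_one_model <- function(x, y, config, seed) {
  if (config$algorithm == "rf") {
    d <- x; d$.y <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = d, probability = TRUE,
      num.trees = config$num_trees, importance = "impurity",
      seed = seed, num.threads = 1
    )
    list(kind = "rf", fit = fit)
  } else {
    enc <- one_hot(x)
    set.seed(seed)
    fit <- nnet::nnet(enc$x, as.numeric(y == "Threatened"),
                      size = config$hidden_units, decay = config$decay,
                      maxit = config$maxit, entropy = TRUE, trace = FALSE,
                      MaxNWts = 1e5)
    list(kind = "ann", fit = fit, scale = enc$info, columns = colnames(enc$x))
  }
}

# probability of Threatened from one model
predict_prob_one <- function(model, x) {
  if (model$kind == "rf") {
    p <- predict(model$fit, data = x, num.threads = 1)$predictions
    p[, "Threatened"]
  } else {
    mm <- stats::model.matrix(~ . - 1, data = x,
                              contrasts.arg = lapply(
                                x[vapply(x, is.factor, logical(1))],
                                stats::contrasts, contrasts = FALSE))
    mm <- mm[, model$columns, drop = FALSE]
    mm <- scale(mm, model$scale$center, model$scale$scale)
    as.numeric(predict(model$fit, mm))
  }
}

predict_one_model <- function(model, x) {
  factor(ifelse(predict_prob_one(model, x) > 0.5, "Threatened", "NonThreatened"),
         levels = c("NonThreatened", "Threatened"))
}

#' @export
print.status_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<status_ensemble> %s, %d subsets x %d folds = %d models\n",
              x$config$algorithm, x$config$n_subsets, x$config$cv_folds, x$n_models))
  cat(sprintf("  held-out: accuracy %.3f, TP %.1f%%, FP %.1f%%, FN %.1f%%\n",
              g$accuracy, g$tp_rate, g$fp_rate, g$fn_rate))
  invisible(x)
}

#' Per-model and aggregate held-out metrics
#'
#' `tidy()` returns one row per (subset, fold) model with its held-out
#' accuracy and the three-way percentage tally; `glance()` aggregates to
#' means and SDs over all models.
#'
#' @param x A `status_ensemble`.
#' @param ... Unused.
#' @export
tidy.status_ensemble <- function(x, ...) x$metrics

#' @rdname tidy.status_ensemble
#' @export
glance.status_ensemble <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    algorithm = x$config$algorithm,
    n_models = x$n_models,
    accuracy = mean(m$accuracy),
    accuracy_sd = sd(m$accuracy),
    tp_rate = mean(m$tp_rate), tp_sd = sd(m$tp_rate),
    fp_rate = mean(m$fp_rate), fp_sd = sd(m$fp_rate),
    fn_rate = mean(m$fn_rate), fn_sd = sd(m$fn_rate)
  )
}

#' Consensus status prediction over an ensemble's models
#'
#' Every model votes on every species; `p` is the fraction of votes for
#' Threatened. A species is called Threatened iff `p` strictly exceeds the
#' consensus threshold tau, Non-Threatened iff `1 - p` strictly exceeds tau,
#' and left uncalled otherwise — so `p` exactly at tau yields `NoCall`.
#' Species with missing feature values are not voted on and are returned as
#' `NoCall` with `reason = "missing_features"`.
#'
#' @param ensemble A [fit_status_ensemble()] object.
#' @param newdata Tibble with `species_id` and the ensemble's features.
#' @param tau Consensus threshold; defaults to the ensemble config's.
#' @return A `vote_table` tibble: `species_id`, `algorithm`,
#'   `votes_threatened`, `votes_total`, `p`, `call`, `reason`.
#' @export
consensus_predict <- function(ensemble, newdata, tau = NULL) {
  stopifnot(inherits(ensemble, "status_ensemble"))
  tau <- tau %||% ensemble$config$consensus_threshold
  x <- encode_features(newdata, ensemble$schema)
  ok <- stats::complete.cases(x)
  votes_t <- rep(NA_integer_, nrow(x))
  total <- length(ensemble$models)
  if (any(ok)) {
    xm <- x[ok, , drop = FALSE]
    vt <- rep(0L, nrow(xm))
    for (m in ensemble$models) {
      vt <- vt + as.integer(predict_prob_one(m, xm) > 0.5)
    }
    votes_t[ok] <- vt
  }
  p <- votes_t / total
  call <- dplyr::case_when(
    !ok ~ "NoCall",
    p > tau ~ "Threatened",
    (1 - p) > tau ~ "NonThreatened",
    .default = "NoCall"
  )
  out <- tibble::tibble(
    species_id = newdata$species_id,
    algorithm = ensemble$config$algorithm,
    votes_threatened = votes_t,
    votes_total = ifelse(ok, total, 0L),
    p = p,
    call = call,
    reason = ifelse(ok, NA_character_, "missing_features")
  )
  structure(out, tau = tau, class = c("vote_table", class(out)))
}
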