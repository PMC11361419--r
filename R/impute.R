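#' Iterative tree-ensemble imputation of a trait table
#'
#' Missing entries are filled by iterating random-forest regressions /
#' classifications over the columns: initialize gaps with the column mean
#' (numeric) or mode (categorical), then sweep the columns in order of
#' increasing missingness, refitting a forest for each target on the
#' currently completed table and re-predicting its missing entries, until
#' the relative change between sweeps drops below `tol` or `max_sweeps`
#' sweeps have run.
#'
#' @param table Data frame of predictor columns (numeric or factor). Other
#'   column types are left untouched and not used as covariates.
#' @param columns Columns to use (default: all numeric/factor columns).
#' @param max_sweeps,tol Convergence controls.
#' @param num_trees Trees per forest.
#' @param seed Seed for the forests.
#' @return The table with missing entries in `columns` filled in. Observed
#'   entries are never altered.
#' @keywords internal
iterative_impute <- function(table, columns = NULL, max_sweeps = 10, tol = 1e-3,
                             num_trees = 100, seed = 1L) {
  df <- as.data.frame(table)
  usable <- names(df)[vapply(df, function(c) is.numeric(c) || is.factor(c), logical(1))]
  columns <- columns %||% usable
  columns <- intersect(columns, usable)
  miss <- lapply(df[columns], function(c) which(is.na(c)))
  targets <- columns[lengths(miss[columns]) > 0]
  if (!length(targets)) return(table)

  cur <- df
  for (cl in usable) {                       # mean/mode initialization
    idx <- which(is.na(cur[[cl]]))
    if (!length(idx)) next
    if (is.numeric(cur[[cl]])) {
      cur[[cl]][idx] <- mean(cur[[cl]], na.rm = TRUE)
    } else {
      cur[[cl]][idx] <- stat_mode(cur[[cl]])
    }
  }
  # columns with anything still NA (entirely missing) cannot participate
  usable <- usable[!vapply(cur[usable], anyNA, logical(1))]
  targets <- targets[vapply(targets, function(cl) {
    cl %in% usable && length(miss[[cl]]) < nrow(cur)
  }, logical(1))]
  targets <- targets[order(lengths(miss[targets]))]
  seeds <- derive_seeds(seed, max(length(targets), 1L) * max_sweeps)

  for (sweep in seq_len(max_sweeps)) {
    change_num <- 0; change_den <- 0; change_cat <- 0; n_cat <- 0
    for (ti in seq_along(targets)) {
      cl <- targets[ti]
      idx <- miss[[cl]]
      covars <- setdiff(usable, cl)
      if (!length(covars)) next
      obs <- setdiff(seq_len(nrow(cur)), idx)
      ytr <- df[[cl]][obs]
      if (is.factor(ytr) && dplyr::n_distinct(droplevels(ytr)) < 2) {
        new_vals <- rep(stat_mode(ytr), length(idx))   # constant column
      } else {
        dtr <- cur[obs, covars, drop = FALSE]
        dtr$.y <- if (is.factor(ytr)) droplevels(ytr) else ytr
        # rich mtry: with few covariates the default sqrt(p) draw too often
        # misses the informative one, degrading deterministic relations
        fit <- ranger::ranger(
          dependent.variable.name = ".y", data = dtr,
          num.trees = num_trees, mtry = max(1L, ceiling(2 * length(covars) / 3)),
          seed = seeds[(sweep - 1L) * length(targets) + ti],
          respect.unordered.factors = "order", num.threads = 1
        )
        new_vals <- predict(fit, data = cur[idx, covars, drop = FALSE],
                            num.threads = 1)$predictions
      }
      old_vals <- cur[[cl]][idx]
      if (is.numeric(cur[[cl]])) {
        change_num <- change_num + sum((as.numeric(new_vals) - as.numeric(old_vals))^2)
        change_den <- change_den + sum(as.numeric(new_vals)^2)
        cur[[cl]][idx] <- as.numeric(new_vals)
      } else {
        new_chr <- as.character(new_vals)
        change_cat <- change_cat + sum(new_chr != as.character(old_vals))
        n_cat <- n_cat + length(idx)
        cur[[cl]][idx] <- factor(new_chr, levels = levels(df[[cl]]))
      }
    }
    delta <- 0
    if (change_den > 0) delta <- delta + change_num / change_den
    if (n_cat > 0) delta <- delta + change_cat / n_cat
    if (delta < tol) break
  }
  out <- table
  for (cl in targets) out[[cl]][miss[[cl]]] <- cur[[cl]][miss[[cl]]]
  out
}

#' Holdout evaluation of the trait imputer
#'
#' Measures, trait by trait, how well the iterative imputer can be trusted:
#' the complete cases are split 80/20, the evaluated trait is masked on the
#' 20% test split, the imputer is run on the combined data, and the masked
#' entries are compared with their true values — R^2 for numeric traits,
#' accuracy for categorical ones.
#'
#' @param table Data frame holding the trait columns.
#' @param traits Trait columns to evaluate (default [trait_names()]
#'   intersected with the table).
#' @param holdout_fraction Fraction of complete cases masked for testing
#'   (default 0.2).
#' @param threshold Performance gate: a trait is imputable iff its holdout
#'   performance strictly exceeds this (default 0.6).
#' @param seed Seed controlling the split and the forests.
#' @param num_trees Trees per forest.
#' @return An `imputation_report` tibble: `trait`, `type`
#'   (`"regression"`/`"classification"`), `performance`, `evaluable`,
#'   `gate` (`"imputed"` or `"left_missing"`).
#' @export
evaluate_imputer <- function(table, traits = NULL, holdout_fraction = 0.2,
                             threshold = 0.6, seed = 1L, num_trees = 100) {
  df <- as.data.frame(table)
  traits <- traits %||% intersect(trait_names(), names(df))
  if (length(traits) < 2) {
    abort("Need at least 2 traits to evaluate the imputer.", class = "riskfill_config_error")
  }
  cc <- which(stats::complete.cases(df[traits]))
  if (length(cc) < 5) {
    abort("Too few complete rows to form a holdout.", class = "riskfill_config_error")
  }
  seeds <- derive_seeds(seed, 1 + length(traits))
  set.seed(seeds[1])
  test <- sample(cc, max(1, round(holdout_fraction * length(cc))))
  train <- setdiff(cc, test)

  rows <- purrr::imap(setNames(traits, traits), function(tr, nm) {
    i <- match(tr, traits)
    col <- df[[tr]]
    if (all(is.na(col))) {
      return(tibble::tibble(trait = tr, type = NA_character_,
                            performance = NA_real_, evaluable = FALSE))
    }
    type <- if (is.numeric(col)) "regression" else "classification"
    work <- df[c(train, test), traits, drop = FALSE]
    masked <- length(train) + seq_along(test)
    truth <- work[[tr]][masked]
    work[[tr]][masked] <- NA
    done <- iterative_impute(work, columns = traits, num_trees = num_trees,
                             seed = seeds[1 + i])
    pred <- done[[tr]][masked]
    perf <- if (type == "regression") {
      sst <- sum((truth - mean(truth))^2)
      if (sst == 0) 1 else 1 - sum((truth - pred)^2) / sst
    } else {
      mean(as.character(truth) == as.character(pred))
    }
    tibble::tibble(trait = tr, type = type, performance = perf, evaluable = TRUE)
  })
  rep <- dplyr::bind_rows(rows)
  rep$gate <- ifelse(rep$evaluable & rep$performance > threshold,
                     "imputed", "left_missing")
  structure(rep, threshold = threshold, class = c("imputation_report", class(rep)))
}

#' Gated imputation of a species trait table
#'
#' Species with more than `max_missing_fields` missing predictor values are
#' excluded first and flagged unpredictable. Then only the traits whose
#' holdout performance strictly exceeds `threshold` (see
#' [evaluate_imputer()]) are imputed; under-performing traits keep their
#' gaps. Observed values are never altered.
#'
#' @param table Data frame with `species_id` and the trait columns.
#' @param report An [evaluate_imputer()] report for the same traits.
#' @param threshold Gate threshold in \[0, 1\] (default 0.6, strict `>`).
#' @param max_missing_fields Exclusion cap on missing predictors per species
#'   (default 6 of the 12).
#' @param seed,num_trees Forest controls.
#' @return A list: `table` (completed tibble, excluded rows dropped),
#'   `excluded` (species ids flagged `"unpredictable"`), `imputed_traits`,
#'   `left_missing`.
#' @export
impute_traits <- function(table, report, threshold = 0.6, max_missing_fields = 6,
                          seed = 1L, num_trees = 100) {
  if (threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1].", class = "riskfill_config_error")
  }
  stopifnot(inherits(report, "imputation_report"))
  traits <- intersect(report$trait, names(table))
  nm <- rowSums(is.na(as.data.frame(table)[traits]))
  excluded <- table$species_id[nm > max_missing_fields]
  kept <- table[nm <= max_missing_fields, , drop = FALSE]

  gated <- report$trait[report$evaluable & report$performance > threshold]
  out <- kept
  if (length(gated) && nrow(kept)) {
    out <- iterative_impute(kept, columns = traits, num_trees = num_trees, seed = seed)
    for (tr in setdiff(traits, gated)) out[[tr]] <- kept[[tr]]   # ungated untouched
  }
  list(
    table = tibble::as_tibble(out),
    excluded = excluded,
    imputed_traits = gated,
    left_missing = setdiff(traits, gated)
  )
}
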