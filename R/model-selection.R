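# Random-forest recursive feature elimination and the RF/LM/LMM
# model-comparison harness.
#
# Cross-validated R^2 is computed per fold on the held-out records,
# R^2 = 1 - SSE/SST, then averaged across folds; folds are a uniform random
# partition with sizes differing by at most one.

#' Assign records to cross-validation folds
#'
#' @param n Number of records.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the random permutation.
#' @return Integer vector of fold indices in `1:n_folds`; fold sizes differ
#'   by at most one.
#' @export
make_cv_folds <- function(n, n_folds = 5, seed = 1L) {
  stopifnot(n >= n_folds)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

rf_mtry_default <- function(k) max(1L, as.integer(floor((k - 1) / 3)))

fit_predict_fold <- function(train, test, target, predictors, model,
                             mtry, min_node_size, n_trees, seed) {
  if (model == "rf") {
    fit <- ranger::ranger(
      x = train[, predictors, drop = FALSE],
      y = train[[target]],
      num.trees = n_trees,
      mtry = min(mtry, length(predictors)),
      min.node.size = min_node_size,
      seed = seed,
      num.threads = 1
    )
    stats::predict(fit, data = test[, predictors, drop = FALSE])$predictions
  } else {
    fml <- stats::reformulate(sprintf("`%s`", predictors), response = target)
    fit <- stats::lm(fml, data = train)
    unname(stats::predict(fit, newdata = test))
  }
}

#' Cross-validated R-squared of a model
#'
#' Fits the model on each training fold and scores
#' `1 - SSE/SST` on the held-out fold, where SST uses the held-out mean.
#' The default metric is the mean of the per-fold scores; `pooled = TRUE`
#' instead computes one R-squared from all out-of-fold predictions.
#'
#' @param data A tibble containing `target` and `predictors` columns with no
#'   missing values.
#' @param target Response column name.
#' @param predictors Character vector of predictor column names.
#' @param model `"rf"` (random forest via ranger) or `"lm"` (ordinary least
#'   squares).
#' @param n_folds Number of CV folds.
#' @param seed Seed controlling fold assignment and forest growth.
#' @param mtry,min_node_size,n_trees Random-forest hyperparameters; `mtry`
#'   defaults to `max(1, floor((K - 1)/3))` for K predictors.
#' @param pooled Compute a single pooled out-of-fold R-squared instead of the
#'   per-fold mean?
#' @return Cross-validated R-squared (may be negative for models worse than
#'   the held-out mean).
#' @export
cv_r2 <- function(data, target, predictors, model = c("rf", "lm"),
                  n_folds = 5, seed = 1L,
                  mtry = NULL, min_node_size = 5, n_trees = 500,
                  pooled = FALSE) {
  model <- match.arg(model)
  used <- data[, c(target, predictors), drop = FALSE]
  if (anyNA(used)) {
    n_before <- nrow(data)
    keep <- stats::complete.cases(used)
    data <- data[keep, , drop = FALSE]
    message(
      "dropped ", n_before - nrow(data),
      " record(s) with missing values before model fitting"
    )
  }
  for (p in predictors) {
    if (any(!is.finite(data[[p]]))) {
      stop("non-finite values in predictor '", p, "'", call. = FALSE)
    }
  }
  if (is.null(mtry)) mtry <- rf_mtry_default(length(predictors))
  folds <- make_cv_folds(nrow(data), n_folds, seed)
  preds <- numeric(nrow(data))
  fold_r2 <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- folds == f
    y_test <- data[[target]][test_idx]
    if (stats::var(y_test) == 0) {
      stop(
        "held-out fold ", f, " has zero target variance; ",
        "use larger folds or more records",
        call. = FALSE
      )
    }
    p <- fit_predict_fold(
      data[!test_idx, , drop = FALSE], data[test_idx, , drop = FALSE],
      target, predictors, model, mtry, min_node_size, n_trees,
      seed = seed + f
    )
    preds[test_idx] <- p
    fold_r2[f] <- 1 - sum((y_test - p)^2) / sum((y_test - mean(y_test))^2)
  }
  if (pooled) {
    y <- data[[target]]
    1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  } else {
    mean(fold_r2)
  }
}

cv_rmse_rf <- function(data, target, predictors, mtry, min_node_size,
                       n_folds, n_trees, seed) {
  folds <- make_cv_folds(nrow(data), n_folds, seed)
  fold_rmse <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- folds == f
    p <- fit_predict_fold(
      data[!test_idx, , drop = FALSE], data[test_idx, , drop = FALSE],
      target, predictors, "rf", mtry, min_node_size, n_trees,
      seed = seed + f
    )
    fold_rmse[f] <- sqrt(mean((data[[target]][test_idx] - p)^2))
  }
  mean(fold_rmse)
}

#' Tune random-forest hyperparameters by cross-validated RMSE
#'
#' Evaluates every grid point by mean root-mean-square error across CV folds
#' and returns the minimizer. Ties are broken toward smaller `mtry`, then
#' larger `min_node_size` (the more regularized forest).
#'
#' @inheritParams cv_r2
#' @param mtry_grid,min_node_size_grid Candidate values.
#' @return A list with the chosen `mtry`, `min_node_size`, `n_trees`,
#'   `cv_rmse`, and the full `grid` tibble of scores.
#' @export
tune_rf <- function(data, target, predictors,
                    mtry_grid = NULL, min_node_size_grid = c(3, 5, 10),
                    n_folds = 5, n_trees = 500, seed = 1L) {
  if (is.null(mtry_grid)) {
    mtry_grid <- unique(pmax(1, pmin(
      length(predictors),
      c(rf_mtry_default(length(predictors)), 2, length(predictors))
    )))
  }
  grid <- tidyr::expand_grid(
    mtry = sort(as.integer(mtry_grid)),
    min_node_size = sort(as.integer(min_node_size_grid), decreasing = TRUE)
  )
  grid$cv_rmse <- purrr::map2_dbl(
    grid$mtry, grid$min_node_size,
    ~ cv_rmse_rf(data, target, predictors, .x, .y, n_folds, n_trees, seed)
  )
  best <- grid[order(grid$cv_rmse, grid$mtry, -grid$min_node_size), ][1, ]
  list(
    mtry = best$mtry, min_node_size = best$min_node_size,
    n_trees = n_trees, cv_rmse = best$cv_rmse, grid = grid
  )
}

#' Recursive feature elimination with random forests
#'
#' Starting from all `predictors`, repeatedly fits candidate forests with one
#' predictor dropped and eliminates the predictor whose removal yields the
#' highest remaining cross-validated R-squared (the smallest performance
#' decrease), down to a single predictor. At a step with K' predictors the
#' forest uses `mtry = max(1, floor((K' - 1)/3))`.
#'
#' @inheritParams cv_r2
#' @return An object of class `"rfe_path"`: a list with `steps` (tibble of
#'   `step`, `n_predictors`, `mtry`, `cv_r2` of the model on the current set,
#'   and `eliminated`, `NA` on the terminal single-predictor row) and
#'   `predictors` (initial set, in input order).
#' @export
rfe <- function(data, target, predictors, n_folds = 5, min_node_size = 5,
                n_trees = 500, seed = 1L) {
  stopifnot(length(predictors) >= 2)
  current <- predictors
  score_for <- function(set) {
    cv_r2(
      data, target, set,
      model = "rf", n_folds = n_folds, seed = seed,
      mtry = rf_mtry_default(length(set)),
      min_node_size = min_node_size, n_trees = n_trees
    )
  }
  steps <- list()
  current_score <- score_for(current)
  step <- 0L
  while (length(current) > 1) {
    step <- step + 1L
    candidate_scores <- vapply(
      seq_along(current),
      function(i) score_for(current[-i]),
      numeric(1)
    )
    drop_i <- which.max(candidate_scores)
    steps[[step]] <- tibble::tibble(
      step = step,
      n_predictors = length(current),
      mtry = rf_mtry_default(length(current)),
      cv_r2 = current_score,
      eliminated = current[drop_i]
    )
    current_score <- candidate_scores[drop_i]
    current <- current[-drop_i]
  }
  steps[[step + 1L]] <- tibble::tibble(
    step = step + 1L, n_predictors = 1L, mtry = 1L,
    cv_r2 = current_score, eliminated = NA_character_
  )
  structure(
    list(steps = dplyr::bind_rows(steps), predictors = predictors),
    class = "rfe_path"
  )
}

#' @export
print.rfe_path <- function(x, ...) {
  cat(
    "Recursive feature elimination over", length(x$predictors),
    "predictors\n"
  )
  print(x$steps, n = Inf)
  invisible(x)
}

#' Predictors retained at a given step of an elimination path
#'
#' @param path An [rfe()] path.
#' @param n_predictors Set size wanted.
#' @return Character vector of the predictors still present when the path
#'   had `n_predictors` left.
#' @export
rfe_set_at <- function(path, n_predictors) {
  eliminated_before <- path$steps$eliminated[
    path$steps$n_predictors > n_predictors & !is.na(path$steps$eliminated)
  ]
  setdiff(path$predictors, eliminated_before)
}

#' Choose a final predictor set from an elimination path
#'
#' Default rule: the smallest set whose cross-validated R-squared is within
#' `tol` of the best score anywhere along the path.
#'
#' @param path An [rfe()] path.
#' @param tol Tolerated drop from the path maximum (R-squared units).
#' @return Character vector of retained predictor names, with attribute
#'   `"rule"` recording the selection rule applied.
#' @export
select_final_set <- function(path, tol = 0.01) {
  steps <- path$steps
  best <- max(steps$cv_r2)
  ok_sizes <- steps$n_predictors[steps$cv_r2 >= best - tol]
  out <- rfe_set_at(path, min(ok_sizes))
  attr(out, "rule") <- sprintf("smallest set with cv_r2 >= max - %g", tol)
  out
}

#' One-hot encode taxonomic identity
#'
#' Builds one indicator column per observed level of species, genus, and
#' family (whichever of the three columns are present), named
#' `species.<level>` etc.
#'
#' @param data A trait dataset tibble.
#' @return A tibble of 0/1 indicator columns, rows aligned with `data`; each
#'   row sums to the number of encoded taxonomic blocks.
#' @export
one_hot_identity <- function(data) {
  blocks <- intersect(c("species", "genus", "family"), names(data))
  stopifnot(length(blocks) >= 1)
  cols <- purrr::map(blocks, function(b) {
    f <- factor(data[[b]])
    m <- vapply(
      levels(f), function(lev) as.numeric(f == lev),
      numeric(length(f))
    )
    if (length(f) == 1) m <- matrix(m, nrow = 1)
    colnames(m) <- paste0(b, ".", levels(f))
    tibble::as_tibble(m)
  })
  dplyr::bind_cols(cols)
}

compare_cell <- function(expr, trait, data_version, model, metric) {
  value <- tryCatch(expr, error = function(e) {
    structure(NA_real_, note = conditionMessage(e))
  })
  note <- attr(value, "note") %||% NA_character_
  tibble::tibble(
    trait = trait, data_version = data_version, model = model,
    metric = metric, value = as.numeric(value), note = note
  )
}

#' Compare RF, LM, and LMM across the three data versions
#'
#' Fills the model-comparison grid: random forests on the full
#' (one-hot identity + environment), site-aggregated, and
#' within-species-centered data; ordinary least squares on the site and
#' within versions; a mixed model with species random intercepts on the full
#' data (reported as marginal R-squared and ICC); a forest with identity
#' predictors only; and the environment-only contribution, the difference
#' between the full forest and the identity-only forest.
#'
#' Traits are natural-log transformed before fitting (within-species
#' centering is then applied on the log scale); the mixed model applies its
#' own Yeo-Johnson transform to the raw trait.
#'
#' @param data A trait dataset tibble (already N:P-filtered).
#' @param predictors Environmental predictor columns (e.g. the RFE
#'   selection).
#' @param traits Trait columns to model.
#' @param n_folds,n_trees,min_node_size,seed Passed to the CV harness.
#' @param log_scale Log-transform traits before RF/LM fitting?
#' @return A tibble grid with columns `trait`, `data_version`
#'   (`full`/`site`/`within`), `model`, `metric`, `value`, `note` (reason a
#'   cell could not be fitted, else `NA`). A failed cell leaves `value = NA`
#'   and the run continues.
#' @export
compare_models <- function(data, predictors,
                           traits = c("leaf_n", "leaf_p", "np_ratio"),
                           n_folds = 5, n_trees = 500, min_node_size = 5,
                           seed = 1L, log_scale = TRUE) {
  logged <- if (log_scale) log_transform_traits(data, traits) else data
  site <- aggregate_sites(logged)
  within <- center_within_species(logged, traits)
  identity_cols <- one_hot_identity(data)
  full_rf <- dplyr::bind_cols(logged, identity_cols)
  id_names <- names(identity_cols)

  rows <- purrr::map(traits, function(tr) {
    lmm_fit <- tryCatch(
      fit_trait_lmm(data, predictors, tr, transform = "yeo-johnson"),
      error = function(e) e
    )
    lmm_rows <- if (inherits(lmm_fit, "error")) {
      dplyr::bind_rows(
        compare_cell(stop(conditionMessage(lmm_fit)), tr, "full", "LMM", "r2_marginal"),
        compare_cell(stop(conditionMessage(lmm_fit)), tr, "full", "LMM", "icc_adjusted")
      )
    } else {
      g <- glance(lmm_fit)
      dplyr::bind_rows(
        compare_cell(g$r2_marginal, tr, "full", "LMM", "r2_marginal"),
        compare_cell(g$icc_adjusted, tr, "full", "LMM", "icc_adjusted")
      )
    }
    rf_full <- compare_cell(
      cv_r2(full_rf, tr, c(predictors, id_names),
        model = "rf",
        n_folds = n_folds, seed = seed, n_trees = n_trees,
        min_node_size = min_node_size
      ),
      tr, "full", "RF", "cv_r2"
    )
    rf_identity <- compare_cell(
      cv_r2(full_rf, tr, id_names,
        model = "rf", n_folds = n_folds,
        seed = seed, n_trees = n_trees, min_node_size = min_node_size
      ),
      tr, "full", "RF_identity_only", "cv_r2"
    )
    env_contrib <- tibble::tibble(
      trait = tr, data_version = "full", model = "RF_env_contribution",
      metric = "delta_cv_r2", value = rf_full$value - rf_identity$value,
      note = NA_character_
    )
    dplyr::bind_rows(
      compare_cell(
        cv_r2(site, tr, predictors,
          model = "rf", n_folds = n_folds,
          seed = seed, n_trees = n_trees, min_node_size = min_node_size
        ),
        tr, "site", "RF", "cv_r2"
      ),
      compare_cell(
        cv_r2(site, tr, predictors,
          model = "lm", n_folds = n_folds,
          seed = seed
        ),
        tr, "site", "LM", "cv_r2"
      ),
      compare_cell(
        cv_r2(within, tr, predictors,
          model = "rf", n_folds = n_folds,
          seed = seed, n_trees = n_trees, min_node_size = min_node_size
        ),
        tr, "within", "RF", "cv_r2"
      ),
      compare_cell(
        cv_r2(within, tr, predictors,
          model = "lm", n_folds = n_folds,
          seed = seed
        ),
        tr, "within", "LM", "cv_r2"
      ),
      rf_full, rf_identity, env_contrib, lmm_rows
    )
  })
  dplyr::bind_rows(rows)
}
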