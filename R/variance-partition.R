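# Mixed-model variance partitioning and the order-dependent linear-model
# decompositions of species vs site vs environment.

#' Fit a species random-intercept mixed model and partition its variance
#'
#' Fits (by REML) a linear mixed model of the trait on the given
#' environmental predictors as fixed effects with a random intercept per
#' species. Predictors are standardized (z-scored) before fitting, so the
#' fixed-effect coefficients are normalized effects and directly comparable;
#' the trait is transformed first (Yeo-Johnson by maximum likelihood, by
#' default). Variance components yield:
#' * marginal R-squared `var_fixed / (var_fixed + var_random + var_resid)` —
#'   the share explained by the environment,
#' * adjusted ICC `var_random / (var_random + var_resid)` and unadjusted ICC
#'   `var_random / (var_fixed + var_random + var_resid)` — the share
#'   attributable to species identity,
#'
#' where `var_fixed` is the variance of the fixed-effect predictions.
#'
#' @param data A trait dataset tibble; needs at least 2 species with at
#'   least 2 records each.
#' @param predictors Environmental predictor columns used as fixed effects.
#' @param trait Trait column to model.
#' @param transform `"yeo-johnson"` (default), `"log"`, or `"none"`.
#' @param group Grouping column for the random intercepts.
#' @return An object of class `"trait_lmm"`; see [tidy.trait_lmm()] for the
#'   per-predictor normalized effects and [glance.trait_lmm()] for the
#'   variance partition.
#' @export
fit_trait_lmm <- function(data, predictors, trait,
                          transform = c("yeo-johnson", "log", "none"),
                          group = "species") {
  transform <- match.arg(transform)
  used <- data[, c(trait, predictors, group), drop = FALSE]
  if (anyNA(used)) {
    n_before <- nrow(data)
    data <- data[stats::complete.cases(used), , drop = FALSE]
    message(
      "dropped ", n_before - nrow(data),
      " record(s) with missing values before model fitting"
    )
  }
  grp_sizes <- table(data[[group]])
  if (sum(grp_sizes >= 2) < 2) {
    stop("need at least 2 groups with at least 2 records each", call. = FALSE)
  }
  y <- switch(transform,
    "yeo-johnson" = yeo_johnson(data[[trait]])$values,
    "log" = log(data[[trait]]),
    "none" = data[[trait]]
  )
  lambda <- if (transform == "yeo-johnson") {
    yeo_johnson(data[[trait]])$lambda
  } else {
    NA_real_
  }
  fit_data <- tibble::tibble(.y = y, .group = factor(data[[group]]))
  for (p in predictors) {
    v <- data[[p]]
    s <- stats::sd(v)
    fit_data[[p]] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  fml <- stats::as.formula(paste(
    ".y ~",
    if (length(predictors)) {
      paste(sprintf("`%s`", predictors), collapse = " + ")
    } else {
      "1"
    },
    "+ (1 | .group)"
  ))
  fit <- lme4::lmer(fml, data = fit_data, REML = TRUE)
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("random-intercept variance is (near) zero; ICC reported as ~0",
      call. = FALSE
    )
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- vc$vcov[vc$grp == ".group"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.numeric(
    stats::model.matrix(fit) %*% lme4::fixef(fit)
  ))
  total <- var_fixed + var_random + var_resid
  coefs <- summary(fit)$coefficients
  resid_df <- nrow(fit_data) - nrow(coefs) - nlevels(fit_data$.group) + 1
  eff <- tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    std_error = coefs[, "Std. Error"],
    t_value = coefs[, "t value"],
    p_value = 2 * stats::pt(abs(coefs[, "t value"]), df = resid_df,
      lower.tail = FALSE
    ),
  ) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(
      term = gsub("`", "", .data$term),
      significant_1pct = .data$p_value < 0.01
    )
  structure(
    list(
      fit = fit,
      partition = tibble::tibble(
        var_fixed = var_fixed, var_random = var_random,
        var_resid = var_resid,
        r2_marginal = var_fixed / total,
        r2_conditional = (var_fixed + var_random) / total,
        icc_adjusted = var_random / (var_random + var_resid),
        icc_unadjusted = var_random / total
      ),
      effects = eff,
      trait = trait, transform = transform, lambda = lambda,
      df_method = "residual-df approximation", resid_df = resid_df
    ),
    class = "trait_lmm"
  )
}

#' @export
print.trait_lmm <- function(x, ...) {
  cat(
    "Species random-intercept LMM for", x$trait,
    sprintf("(transform: %s)\n", x$transform)
  )
  print(x$partition)
  invisible(x)
}

#' Normalized fixed effects of a fitted trait mixed model
#'
#' @param x A [fit_trait_lmm()] object.
#' @param ... Unused.
#' @return A tibble with one row per predictor: `term`, `estimate` (on the
#'   standardized predictor scale), `std_error`, `t_value`, `p_value`
#'   (residual-df approximation), and `significant_1pct`.
#' @method tidy trait_lmm
#' @export
tidy.trait_lmm <- function(x, ...) {
  x$effects
}

#' Variance partition of a fitted trait mixed model
#'
#' @param x A [fit_trait_lmm()] object.
#' @param ... Unused.
#' @return A one-row tibble: variance components, marginal and conditional
#'   R-squared, and both ICC flavors.
#' @method glance trait_lmm
#' @export
glance.trait_lmm <- function(x, ...) {
  x$partition
}

#' Sequential ANOVA with species fitted before vs after the environment
#'
#' Fits the same linear model twice — `trait ~ species + env` and
#' `trait ~ env + species` — and returns both sequential (type-I)
#' sum-of-squares tables. When species identity and environment are
#' correlated, the species sum of squares depends on the order, which is the
#' mechanism by which random-intercept models absorb shared variance.
#'
#' @param data A trait dataset tibble.
#' @param predictors Environmental predictor columns.
#' @param trait Trait column.
#' @return A list with tibbles `species_first` and `species_last` (columns
#'   `term`, `df`, `sum_sq`) and `total_ss`.
#' @export
anova_order <- function(data, predictors, trait) {
  env_terms <- sprintf("`%s`", predictors)
  d <- dplyr::mutate(data, species = factor(.data$species))
  f1 <- stats::as.formula(paste(
    sprintf("`%s`", trait), "~ species +", paste(env_terms, collapse = " + ")
  ))
  f2 <- stats::as.formula(paste(
    sprintf("`%s`", trait), "~", paste(env_terms, collapse = " + "), "+ species"
  ))
  tidy_anova <- function(fml) {
    tab <- stats::anova(stats::lm(fml, data = d))
    tibble::tibble(
      term = gsub("`", "", rownames(tab)),
      df = tab$Df,
      sum_sq = tab$`Sum Sq`
    )
  }
  first <- tidy_anova(f1)
  last <- tidy_anova(f2)
  list(
    species_first = first,
    species_last = last,
    total_ss = sum(first$sum_sq)
  )
}

r2_of_lm <- function(fml, data) {
  summary(stats::lm(fml, data = data))$r.squared
}

#' Individual and shared explained variance of two grouping factors
#'
#' Commonality partition for two predictors from three least-squares fits:
#' with R2(A), R2(B), and R2(A+B),
#' `individual_a = R2(A+B) - R2(B)`, `individual_b = R2(A+B) - R2(A)`,
#' `shared = R2(A) + R2(B) - R2(A+B)`, `unexplained = 1 - R2(A+B)`.
#' A negative shared component indicates suppression and is flagged.
#'
#' @param data A trait dataset tibble.
#' @param trait Trait column.
#' @param factor_a,factor_b Grouping columns (default site and species).
#' @return A one-row tibble: `individual_site` (factor a), `individual_species`
#'   (factor b), `shared`, `unexplained`, `suppression` flag. The four
#'   proportions sum to 1.
#' @export
shared_effects <- function(data, trait, factor_a = "site_id",
                           factor_b = "species") {
  for (f in c(factor_a, factor_b)) {
    if (dplyr::n_distinct(data[[f]]) < 2) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  d <- tibble::tibble(
    .y = data[[trait]],
    .a = factor(data[[factor_a]]),
    .b = factor(data[[factor_b]])
  )
  r2_a <- r2_of_lm(.y ~ .a, d)
  r2_b <- r2_of_lm(.y ~ .b, d)
  r2_ab <- r2_of_lm(.y ~ .a + .b, d)
  shared <- r2_a + r2_b - r2_ab
  tibble::tibble(
    individual_site = r2_ab - r2_b,
    individual_species = r2_ab - r2_a,
    shared = shared,
    unexplained = 1 - r2_ab,
    suppression = shared < 0
  )
}
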