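# Trait gradient analysis: species-specific OLS regressions against
# community site means, slope distributions, occurrence ranges, and the
# species-variation decomposition.

#' Community site means of a (log) trait
#'
#' Arithmetic mean of the trait over all records at each site, focal species
#' included. On the log scale (the default for the gradient regressions)
#' this is the log geometric mean of the original concentrations.
#'
#' @param data A trait dataset tibble, normally already occurrence-filtered.
#' @param trait Trait column.
#' @param scale `"log"` (default) or `"raw"`.
#' @return Tibble with `site_id` and `site_mean`.
#' @export
tga_site_means <- function(data, trait, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  vals <- if (scale == "log") log(data[[trait]]) else data[[trait]]
  tibble::tibble(site_id = data$site_id, .v = vals) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(site_mean = mean(.data$.v), .groups = "drop")
}

#' Species-specific regressions against community site means
#'
#' For each species, ordinary least squares of its individual log trait
#' values on the log-scale site means of the sites where it occurs. A slope
#' near 0 means the species holds its trait fixed while the community mean
#' changes (the fixed-niche world); a slope near 1 means its trait tracks
#' the community gradient (full plasticity); slopes above 1 indicate
#' overexpression of the gradient.
#'
#' @param data A trait dataset tibble, already occurrence-filtered
#'   (see [filter_occurrence()]).
#' @param trait Trait column.
#' @param site_means Optional precomputed [tga_site_means()]; computed from
#'   `data` when `NULL`.
#' @return A tibble of class `"tga_fits"`, one row per species: `species`,
#'   `trait`, `slope`, `intercept`, `slope_se`, `ci_low`, `ci_high`
#'   (95% CI), `n_points`. Species with fewer than 2 distinct site means are
#'   skipped with a warning.
#' @export
fit_species_regressions <- function(data, trait, site_means = NULL) {
  if (is.null(site_means)) site_means <- tga_site_means(data, trait)
  d <- data |>
    dplyr::mutate(.y = log(.data[[trait]])) |>
    dplyr::left_join(site_means, by = "site_id")
  fits <- d |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(g, key) {
      if (dplyr::n_distinct(g$site_mean) < 2) {
        return(tibble::tibble(
          species = key$species, trait = trait, slope = NA_real_,
          intercept = NA_real_, slope_se = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, n_points = nrow(g)
        ))
      }
      fit <- stats::lm(.y ~ site_mean, data = g)
      est <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))[2]
      tcrit <- stats::qt(0.975, df = fit$df.residual)
      tibble::tibble(
        species = key$species, trait = trait,
        slope = unname(est[2]), intercept = unname(est[1]),
        slope_se = unname(se),
        ci_low = unname(est[2] - tcrit * se),
        ci_high = unname(est[2] + tcrit * se),
        n_points = nrow(g)
      )
    }) |>
    dplyr::bind_rows()
  skipped <- sum(is.na(fits$slope))
  if (skipped > 0) {
    warning(
      skipped, " species with constant site means skipped",
      call. = FALSE
    )
    fits <- fits[!is.na(fits$slope), , drop = FALSE]
  }
  class(fits) <- c("tga_fits", class(fits))
  fits
}

#' Mode and density of the plasticity-slope distribution
#'
#' Gaussian kernel density with Silverman's bandwidth, evaluated on a
#' 512-point grid spanning one bandwidth beyond the observed slope range;
#' the mode is the grid argmax.
#'
#' @param fits A [fit_species_regressions()] result (or tibble with `slope`).
#' @return A list with `mode`, and `density` (tibble `slope`, `density`).
#' @export
slope_distribution <- function(fits) {
  slopes <- fits$slope[is.finite(fits$slope)]
  bw <- stats::bw.nrd0(slopes)
  dens <- stats::density(
    slopes,
    bw = bw, kernel = "gaussian", n = 512,
    from = min(slopes) - bw, to = max(slopes) + bw
  )
  list(
    mode = dens$x[which.max(dens$y)],
    density = tibble::tibble(slope = dens$x, density = dens$y)
  )
}

#' Species occurrence ranges of site-mean trait values
#'
#' For each species, the spread (difference between the 1% and 99% quantiles,
#' linear-interpolation rule) of the original-scale site-mean trait values
#' over the sites where it occurs — a proxy for the breadth of community
#' contexts the species tolerates. `range_norm` divides by the same 1-99%
#' spread of all site means (`normalization = "range"`), so a species
#' occupying the full gradient has `range_norm = 1`; the alternative
#' normalization divides by the overall mean of site means.
#'
#' @param data A trait dataset tibble (occurrence-filtered).
#' @param trait Trait column.
#' @param normalization `"range"` (default) or `"mean"`.
#' @return Tibble per species: `species`, `trait`, `range_raw`, `range_norm`,
#'   `n_sites`.
#' @export
species_ranges <- function(data, trait, normalization = c("range", "mean")) {
  normalization <- match.arg(normalization)
  site_means <- tga_site_means(data, trait, scale = "raw")
  q_range <- function(v) {
    unname(diff(stats::quantile(v, c(0.01, 0.99), type = 7)))
  }
  denom <- switch(normalization,
    range = q_range(site_means$site_mean),
    mean = mean(site_means$site_mean)
  )
  data |>
    dplyr::distinct(.data$species, .data$site_id) |>
    dplyr::left_join(site_means, by = "site_id") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      trait = trait,
      range_raw = q_range(.data$site_mean),
      range_norm = range_raw / denom,
      n_sites = dplyr::n(),
      .groups = "drop"
    )
}

#' Pairwise correlation of species occurrence ranges across traits
#'
#' @param ranges Row-bound [species_ranges()] results for several traits.
#' @return Tibble of trait pairs with the Pearson correlation of
#'   per-species ranges (species present for both traits).
#' @export
range_correlations <- function(ranges) {
  wide <- ranges |>
    dplyr::select("species", "trait", "range_norm") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "range_norm")
  traits <- setdiff(names(wide), "species")
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    both <- stats::complete.cases(wide[, p])
    a <- wide[[p[1]]][both]
    b <- wide[[p[2]]][both]
    # constant ranges (e.g. every species occupying every site) have no
    # correlation to speak of
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      NA_real_
    } else {
      stats::cor(a, b)
    }
    tibble::tibble(
      trait_a = p[1], trait_b = p[2], pearson_r = r, n_species = sum(both)
    )
  })
}

#' Decompose trait variation into across- and within-species shares
#'
#' Compares observed values with two modified datasets: one keeping only
#' across-species variation (values replaced by species means) and one
#' keeping only within-species variation (species-centered, recentered on
#' the global mean). The squared Pearson correlations with the observed
#' series are the across- and within-species shares; they sum to one, and
#' the across share equals the between-species sum of squares over the total
#' (the one-way ANOVA identity).
#'
#' @param data A trait dataset tibble (normally the TGA-filtered subset).
#' @param trait Trait column.
#' @param scale `"log"` (default) or `"raw"`.
#' @return A one-row tibble: `trait`, `r2_across`, `r2_within`,
#'   `global_mean`, `n_records`, `n_species`, and flags
#'   `across_degenerate` / `within_degenerate` set when the corresponding
#'   modified series has zero variance (its share is then reported as 0 and
#'   the other as 1).
#' @export
species_variation_decomposition <- function(data, trait,
                                            scale = c("log", "raw")) {
  scale <- match.arg(scale)
  if (dplyr::n_distinct(data$species) < 2) {
    stop("species variation decomposition needs at least 2 species",
      call. = FALSE
    )
  }
  d <- data
  if (scale == "log") d <- log_transform_traits(d, trait)
  obs <- d[[trait]]
  across <- replace_with_species_means(d, trait)[[trait]]
  within <- normalize_to_global_mean(d, trait)[[trait]]
  # a modified series whose variance is numerically zero relative to the
  # observed variance carries no signal (guards against float residue after
  # mean-equalization)
  v_obs <- stats::var(obs)
  across_degenerate <- stats::var(across) <= 1e-10 * v_obs
  within_degenerate <- stats::var(within) <= 1e-10 * v_obs
  r2_across <- if (across_degenerate) 0 else stats::cor(obs, across)^2
  r2_within <- if (within_degenerate) 0 else stats::cor(obs, within)^2
  tibble::tibble(
    trait = trait,
    r2_across = r2_across,
    r2_within = r2_within,
    global_mean = mean(obs),
    n_records = nrow(d),
    n_species = dplyr::n_distinct(d$species),
    across_degenerate = across_degenerate,
    within_degenerate = within_degenerate
  )
}

#' Full trait gradient analysis for one or more traits
#'
#' Applies the occurrence filter (unless `filtered = TRUE`), then for each
#' trait fits the species-specific gradient regressions, estimates the
#' slope-density mode, computes occurrence ranges and their cross-trait
#' correlations, and runs the species-variation decomposition.
#'
#' @param data A trait dataset tibble (N:P-filtered).
#' @param traits Trait columns to analyze.
#' @param min_sites_per_species,min_species_per_site Occurrence-filter
#'   thresholds.
#' @param filtered Set `TRUE` when `data` is already occurrence-filtered.
#' @param normalization Range normalization rule, see [species_ranges()].
#' @return An object of class `"tga"`: list with `fits` (all traits
#'   row-bound), `summary` (per-trait mode, median slope, median normalized
#'   range), `densities`, `ranges`, `range_correlations`, `decomposition`,
#'   and `n_records`/`n_species` of the analysis subset.
#' @export
tga <- function(data, traits = c("leaf_n", "leaf_p", "np_ratio"),
                min_sites_per_species = 5, min_species_per_site = 5,
                filtered = FALSE, normalization = "range") {
  sub <- if (filtered) {
    data
  } else {
    filter_occurrence(data, min_sites_per_species, min_species_per_site)
  }
  fits <- purrr::map(traits, ~ fit_species_regressions(sub, .x))
  dens <- purrr::map(fits, slope_distribution)
  ranges <- purrr::map_dfr(
    traits,
    ~ species_ranges(sub, .x, normalization = normalization)
  )
  decomposition <- purrr::map_dfr(
    traits,
    ~ species_variation_decomposition(sub, .x)
  )
  summary <- purrr::map2_dfr(fits, dens, function(f, d) {
    rng <- ranges[ranges$trait == f$trait[1], ]
    tibble::tibble(
      trait = f$trait[1],
      n_species = nrow(f),
      slope_mode = d$mode,
      slope_median = stats::median(f$slope),
      range_norm_median = stats::median(rng$range_norm)
    )
  })
  structure(
    list(
      fits = dplyr::bind_rows(fits),
      summary = summary,
      densities = stats::setNames(purrr::map(dens, "density"), traits),
      ranges = ranges,
      range_correlations = if (length(traits) >= 2) {
        range_correlations(ranges)
      } else {
        NULL
      },
      decomposition = decomposition,
      n_records = nrow(sub),
      n_species = dplyr::n_distinct(sub$species)
    ),
    class = "tga"
  )
}

#' @export
print.tga <- function(x, ...) {
  cat(
    "Trait gradient analysis:", x$n_records, "records,",
    x$n_species, "species\n"
  )
  print(x$summary)
  invisible(x)
}

#' Per-species gradient regressions of a trait gradient analysis
#'
#' @param x A [tga()] object.
#' @param ... Unused.
#' @return The row-bound per-species fit tibble.
#' @method tidy tga
#' @export
tidy.tga <- function(x, ...) {
  tibble::as_tibble(x$fits)
}

#' One-row-per-trait summary of a trait gradient analysis
#'
#' @param x A [tga()] object.
#' @param ... Unused.
#' @return Tibble joining the slope mode/median and range medians with the
#'   species-variation decomposition.
#' @method glance tga
#' @export
glance.tga <- function(x, ...) {
  dplyr::left_join(
    x$summary,
    dplyr::select(x$decomposition, "trait", "r2_across", "r2_within"),
    by = "trait"
  )
}
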