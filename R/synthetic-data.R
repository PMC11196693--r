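# Hierarchical synthetic trait generator.
#
# Generative model, per trait, on the natural-log scale:
#
#   x_ij = mu + a_i + beta_i * (m_j - mbar_i) + eps_ij
#   m_j  = sum_c w_c * g_c(E_cj) + sigma_m_latent * eta_j
#
# where m_j is the latent site gradient (partly or wholly composed of
# covariate effects g_c, linear or a threshold interaction), a_i the species
# baseline (optionally aligned with the species' niche centre), beta_i the
# species plasticity slope, and mbar_i the gradient mean over the sites the
# species occupies. Values are exponentiated to positive concentrations, so
# the downstream log transform recovers the linear structure exactly.

#' Specify an environmental covariate for the generator
#'
#' @param name Column name.
#' @param effect Contribution weight to the site gradient; 0 marks a pure
#'   noise covariate.
#' @param form `"linear"` (contributes `effect * E`) or `"nonlinear"`.
#'   Nonlinear covariates are consumed in consecutive pairs contributing
#'   `effect_first * sign(E_a * E_b)` — a threshold interaction with zero
#'   linear projection on either member.
#' @return A one-row tibble covariate spec.
#' @export
cov_spec <- function(name, effect = 0, form = c("linear", "nonlinear")) {
  form <- match.arg(form)
  tibble::tibble(
    name = name, informative = effect != 0, effect = effect, form = form
  )
}

#' Build a synthetic-data configuration
#'
#' @param n_species,n_sites Numbers of species and sites (both >= 1).
#' @param occupancy One of `list(type = "all")` (every species at every
#'   site), `list(type = "fixed", sites_per_species = k)` (uniform random
#'   sample of k sites), or `list(type = "niche", width = w)` (contiguous
#'   window covering fraction `w` of the gradient-ranked sites — emulates
#'   environmental filtering).
#' @param slope_dist True plasticity-slope distribution:
#'   `list(type = "point", value = b)` or `list(type = "normal", mean, sd)`.
#' @param sigma_species SD of species baseline deviations (log scale).
#' @param niche_alignment Coefficient linking a species' baseline to its
#'   realized niche-centre gradient value; > 0 makes species stoichiometry
#'   match the sites they occupy (the fixed-niche world).
#' @param sigma_resid Residual SD (log scale).
#' @param covariates Row-bound [cov_spec()] tibble, or `NULL` for none.
#' @param sigma_m_latent SD of the latent (covariate-independent) part of the
#'   site gradient.
#' @param gradient_sd Overall scaling applied to no-covariate gradients; when
#'   covariates carry the gradient this is ignored and `sigma_m_latent` plus
#'   the covariate weights set the spread.
#' @param mu Grand mean of the log trait (default `log(20)`, a typical leaf N
#'   concentration in mg g^-1).
#' @param mu_p Grand mean of the log leaf P trait (default `log(1.5)`).
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `"trait_sim_config"`.
#' @export
trait_sim_config <- function(n_species,
                             n_sites,
                             occupancy = list(type = "all"),
                             slope_dist = list(type = "point", value = 1),
                             sigma_species = 0.3,
                             niche_alignment = 0,
                             sigma_resid = 0.1,
                             covariates = NULL,
                             sigma_m_latent = 0,
                             gradient_sd = 0.4,
                             mu = log(20),
                             mu_p = log(1.5),
                             seed = 1L) {
  stopifnot(n_species >= 1, n_sites >= 1, sigma_species >= 0, sigma_resid >= 0)
  if (identical(occupancy$type, "niche")) {
    stopifnot(occupancy$width > 0, occupancy$width <= 1)
    if (max(1, round(occupancy$width * n_sites)) > n_sites) {
      stop("niche window needs more sites than exist", call. = FALSE)
    }
  }
  if (identical(occupancy$type, "fixed")) {
    stopifnot(
      occupancy$sites_per_species >= 1,
      occupancy$sites_per_species <= n_sites
    )
  }
  structure(
    list(
      n_species = n_species, n_sites = n_sites, occupancy = occupancy,
      slope_dist = slope_dist, sigma_species = sigma_species,
      niche_alignment = niche_alignment, sigma_resid = sigma_resid,
      covariates = covariates, sigma_m_latent = sigma_m_latent,
      gradient_sd = gradient_sd, mu = mu, mu_p = mu_p, seed = as.integer(seed)
    ),
    class = "trait_sim_config"
  )
}

draw_slopes <- function(dist, n) {
  switch(dist$type,
    point = rep(dist$value, n),
    normal = stats::rnorm(n, dist$mean, dist$sd),
    stop("unknown slope distribution type: ", dist$type, call. = FALSE)
  )
}

# Gradient contribution of the covariates at each site.
covariate_gradient <- function(cov_spec, E) {
  if (is.null(cov_spec) || nrow(cov_spec) == 0) {
    return(rep(0, nrow(E)))
  }
  g <- rep(0, nrow(E))
  lin <- cov_spec[cov_spec$form == "linear" & cov_spec$informative, , drop = FALSE]
  for (k in seq_len(nrow(lin))) {
    g <- g + lin$effect[k] * E[[lin$name[k]]]
  }
  nl <- cov_spec[cov_spec$form == "nonlinear" & cov_spec$informative, , drop = FALSE]
  if (nrow(nl) >= 2) {
    for (k in seq(1, nrow(nl) - 1, by = 2)) {
      g <- g + nl$effect[k] * sign(E[[nl$name[k]]] * E[[nl$name[k + 1]]])
    }
  }
  g
}

occupancy_sites <- function(config, site_rank) {
  n_sites <- config$n_sites
  n_species <- config$n_species
  occ <- config$occupancy
  if (identical(occ$type, "all")) {
    return(lapply(seq_len(n_species), function(i) seq_len(n_sites)))
  }
  if (identical(occ$type, "fixed")) {
    return(lapply(seq_len(n_species), function(i) {
      sort(sample.int(n_sites, occ$sites_per_species))
    }))
  }
  if (identical(occ$type, "niche")) {
    w <- max(1L, as.integer(round(occ$width * n_sites)))
    # contiguous windows in gradient rank order, centres spread evenly with
    # random jitter so neighbouring species overlap
    starts_max <- n_sites - w + 1L
    centres <- seq(0, 1, length.out = n_species)
    jitter <- stats::runif(n_species, -0.5 / n_species, 0.5 / n_species)
    starts <- pmin(pmax(
      1L + as.integer(round((centres + jitter) * (starts_max - 1L))), 1L
    ), starts_max)
    ranked <- order(site_rank) # site indices sorted by gradient
    return(lapply(seq_len(n_species), function(i) {
      sort(ranked[starts[i]:(starts[i] + w - 1L)])
    }))
  }
  stop("unknown occupancy type: ", config$occupancy$type, call. = FALSE)
}

generate_one_trait <- function(config, mu, m, species_sites) {
  n_species <- config$n_species
  beta <- draw_slopes(config$slope_dist, n_species)
  centre <- vapply(species_sites, function(s) mean(m[s]), numeric(1))
  a <- config$niche_alignment * centre +
    stats::rnorm(n_species, 0, config$sigma_species)
  rows <- purrr::map(seq_len(n_species), function(i) {
    s <- species_sites[[i]]
    eps <- stats::rnorm(length(s), 0, config$sigma_resid)
    tibble::tibble(
      species_idx = i,
      site_idx = s,
      log_value = mu + a[i] + beta[i] * (m[s] - centre[i]) + eps
    )
  })
  list(values = dplyr::bind_rows(rows), beta = beta, baseline = a)
}

#' Generate a synthetic trait dataset with known ground truth
#'
#' Draws leaf N and leaf P on the log scale from the hierarchical model
#' described in the package vignette (species baselines, species-specific
#' plasticity along a latent site gradient, optional covariate-driven
#' gradient components and niche-window occupancy), exponentiates to
#' positive concentrations, and derives N:P. Leaf P shares the occupancy
#' pattern and site gradient with leaf N but has its own baselines, slopes,
#' and residuals. The same seed reproduces the output bit for bit.
#'
#' @param config A [trait_sim_config()].
#' @return A list with `data` (trait dataset tibble) and `truth`, a list with
#'   `true_slopes` (per-species tibble of realized leaf N and P slopes),
#'   `true_within_fraction` (per-trait realized within-species share of the
#'   log-scale sum of squares), `true_informative_set`, and `site_gradient`.
#' @export
generate_trait_data <- function(config) {
  stopifnot(inherits(config, "trait_sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  # named per-component streams derived from the master seed
  streams <- sample.int(.Machine$integer.max - 1L, 5)

  set.seed(streams[1])
  cov_names <- if (is.null(config$covariates)) character() else config$covariates$name
  E <- tibble::as_tibble(
    stats::setNames(
      lapply(cov_names, function(nm) stats::rnorm(config$n_sites)),
      cov_names
    )
  )
  if (length(cov_names) == 0) E <- tibble::tibble(.rows = config$n_sites)

  set.seed(streams[2])
  m <- covariate_gradient(config$covariates, E) +
    stats::rnorm(config$n_sites, 0, config$sigma_m_latent)
  if (length(cov_names) == 0 && config$sigma_m_latent == 0) {
    m <- stats::rnorm(config$n_sites, 0, config$gradient_sd)
  }

  set.seed(streams[3])
  species_sites <- occupancy_sites(config, rank(m, ties.method = "first"))

  set.seed(streams[4])
  gen_n <- generate_one_trait(config, config$mu, m, species_sites)
  set.seed(streams[5])
  gen_p <- generate_one_trait(config, config$mu_p, m, species_sites)

  species_lab <- sprintf("sp%03d", seq_len(config$n_species))
  site_lab <- sprintf("site%03d", seq_len(config$n_sites))
  joined <- dplyr::inner_join(
    dplyr::rename(gen_n$values, log_n = "log_value"),
    dplyr::rename(gen_p$values, log_p = "log_value"),
    by = c("species_idx", "site_idx")
  )
  data <- joined |>
    dplyr::transmute(
      species = species_lab[.data$species_idx],
      genus = sprintf("gen%03d", ((.data$species_idx - 1) %/% 4) + 1),
      family = sprintf("fam%03d", ((.data$species_idx - 1) %/% 12) + 1),
      site_id = site_lab[.data$site_idx],
      leaf_n = exp(.data$log_n),
      leaf_p = exp(.data$log_p)
    ) |>
    dplyr::arrange(.data$species, .data$site_id)
  if (length(cov_names) > 0) {
    Ej <- dplyr::mutate(E, site_id = site_lab)
    data <- dplyr::left_join(data, Ej, by = "site_id")
  }
  data <- as_trait_data(data)

  within_fraction <- function(vals, sp) {
    tot <- sum((vals - mean(vals))^2)
    if (tot == 0) {
      return(0)
    }
    centred <- vals - stats::ave(vals, sp)
    sum(centred^2) / tot
  }
  log_n <- log(data$leaf_n)
  log_p <- log(data$leaf_p)
  truth <- list(
    true_slopes = tibble::tibble(
      species = species_lab,
      slope_leaf_n = gen_n$beta,
      slope_leaf_p = gen_p$beta,
      baseline_leaf_n = gen_n$baseline,
      baseline_leaf_p = gen_p$baseline
    ),
    true_within_fraction = c(
      leaf_n = within_fraction(log_n, data$species),
      leaf_p = within_fraction(log_p, data$species),
      np_ratio = within_fraction(log_n - log_p, data$species)
    ),
    true_informative_set = if (is.null(config$covariates)) {
      character()
    } else {
      config$covariates$name[config$covariates$informative]
    },
    site_gradient = stats::setNames(m, site_lab)
  )
  list(data = data, truth = truth)
}

#' Named study scenarios for the generator
#'
#' Each scenario is a fully specified [trait_sim_config()] with a fixed
#' default seed:
#' * `"fig1a_niche"` — fixed-stoichiometry world: zero plasticity slopes,
#'   narrow contiguous niche windows, species baselines aligned with their
#'   niche centre, so all site-level structure arises from species turnover.
#' * `"fig1b_plastic"` — full-plasticity world: slope 1 for every species,
#'   all species at all sites, one informative linear covariate carrying the
#'   gradient.
#' * `"rf_vs_lm_nonlinear"` — within-species environmental signal is a
#'   threshold interaction of two covariates (zero linear projection), plus a
#'   weak linear covariate and noise covariates.
#' * `"icc_recovery"` — pure random-intercept structure (no gradient effect),
#'   species baseline variance 3x the residual variance.
#' * `"rfe_signal"` — 3 informative linear covariates among 12, for feature
#'   selection studies.
#'
#' @param name Scenario name.
#' @param seed Master seed override.
#' @return A `trait_sim_config`.
#' @export
make_scenario <- function(name = c(
                            "fig1a_niche", "fig1b_plastic",
                            "rf_vs_lm_nonlinear", "icc_recovery",
                            "rfe_signal"
                          ),
                          seed = NULL) {
  name <- match.arg(name)
  config <- switch(name,
    fig1a_niche = trait_sim_config(
      n_species = 60, n_sites = 80,
      occupancy = list(type = "niche", width = 0.2),
      slope_dist = list(type = "point", value = 0),
      sigma_species = 0.15, niche_alignment = 0.8,
      sigma_resid = 0.05, gradient_sd = 0.4, seed = 101L
    ),
    fig1b_plastic = trait_sim_config(
      n_species = 50, n_sites = 60,
      occupancy = list(type = "all"),
      slope_dist = list(type = "point", value = 1),
      sigma_species = 0.3, sigma_resid = 0.05,
      covariates = cov_spec("e1", effect = 0.3),
      sigma_m_latent = 0, seed = 102L
    ),
    rf_vs_lm_nonlinear = trait_sim_config(
      n_species = 40, n_sites = 80,
      occupancy = list(type = "all"),
      slope_dist = list(type = "normal", mean = 1, sd = 0.1),
      sigma_species = 0.3, sigma_resid = 0.1,
      covariates = dplyr::bind_rows(
        cov_spec("e1", effect = 0.5, form = "nonlinear"),
        cov_spec("e2", effect = 0.5, form = "nonlinear"),
        cov_spec("e3", effect = 0.15),
        cov_spec("x1"), cov_spec("x2"), cov_spec("x3")
      ),
      sigma_m_latent = 0.05, seed = 103L
    ),
    icc_recovery = trait_sim_config(
      n_species = 200, n_sites = 50,
      occupancy = list(type = "fixed", sites_per_species = 10),
      slope_dist = list(type = "point", value = 0),
      sigma_species = sqrt(0.3), sigma_resid = sqrt(0.1),
      gradient_sd = 0, seed = 104L
    ),
    rfe_signal = trait_sim_config(
      n_species = 40, n_sites = 120,
      occupancy = list(type = "all"),
      slope_dist = list(type = "point", value = 1),
      sigma_species = 0.25, sigma_resid = 0.1,
      covariates = dplyr::bind_rows(
        cov_spec("e1", effect = 0.5),
        cov_spec("e2", effect = 0.35),
        cov_spec("e3", effect = 0.25),
        purrr::map(sprintf("x%d", 1:9), cov_spec)
      ),
      sigma_m_latent = 0.1, seed = 105L
    )
  )
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config
}
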