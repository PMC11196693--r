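test_that("site means match a brute-force group-by, focal species included", {
  d <- as_trait_data(tibble::tibble(
    species = c("A", "B", "C"), site_id = c("s1", "s1", "s2"),
    leaf_n = exp(c(1, 3, 2)), leaf_p = 1
  ))
  sm <- tga_site_means(d, "leaf_n")
  expect_equal(sm$site_mean[sm$site_id == "s1"], 2) # mean of logs 1, 3
  expect_equal(sm$site_mean[sm$site_id == "s2"], 2) # single-record site

  sim <- generate_trait_data(trait_sim_config(
    n_species = 20, n_sites = 30,
    occupancy = list(type = "fixed", sites_per_species = 10), seed = 12
  ))
  sm <- tga_site_means(sim$data, "leaf_n")
  oracle <- tapply(log(sim$data$leaf_n), sim$data$site_id, mean)
  expect_equal(sm$site_mean, as.numeric(oracle[sm$site_id]), tolerance = 1e-12)
})

test_that("species regressions are exact OLS with the usual CI", {
  # hand-computed: points (1, 1.5), (2, 3.5), (3, 5.5) -> slope 2,
  # intercept -0.5; inject via exp so the internal log recovers them
  d <- as_trait_data(tibble::tibble(
    species = "A", site_id = c("s1", "s2", "s3"),
    leaf_n = exp(c(1.5, 3.5, 5.5)), leaf_p = 1
  ))
  sm <- tibble::tibble(site_id = c("s1", "s2", "s3"), site_mean = c(1, 2, 3))
  fit <- suppressWarnings(fit_species_regressions(d, "leaf_n", site_means = sm))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, -0.5, tolerance = 1e-10)
  expect_true(fit$ci_low <= fit$slope & fit$slope <= fit$ci_high)

  # noise-free plastic world: slope exactly 1; fixed-niche world: exactly 0
  cfg1 <- make_scenario("fig1b_plastic")
  cfg1$sigma_resid <- 0
  f1 <- suppressWarnings(
    fit_species_regressions(generate_trait_data(cfg1)$data, "leaf_n")
  )
  expect_equal(f1$slope, rep(1, nrow(f1)), tolerance = 1e-8)

  cfg0 <- make_scenario("fig1a_niche")
  cfg0$sigma_resid <- 0
  d0 <- filter_occurrence(generate_trait_data(cfg0)$data)
  f0 <- suppressWarnings(fit_species_regressions(d0, "leaf_n"))
  expect_equal(f0$slope, rep(0, nrow(f0)), tolerance = 1e-8)
})

test_that("slopes are invariant to log base and unit rescaling", {
  sim <- generate_trait_data(trait_sim_config(
    n_species = 15, n_sites = 15,
    slope_dist = list(type = "normal", mean = 1, sd = 0.3),
    sigma_resid = 0.05, seed = 14
  ))
  f_ln <- fit_species_regressions(sim$data, "leaf_n")
  # log10 on both axes: slope of the regression is unchanged
  d10 <- sim$data
  sm10 <- tibble::tibble(
    site_id = tga_site_means(d10, "leaf_n")$site_id,
    site_mean = tga_site_means(d10, "leaf_n")$site_mean / log(10)
  )
  f_10 <- dplyr::group_by(
    dplyr::left_join(
      dplyr::mutate(d10, y10 = log10(leaf_n)), sm10,
      by = "site_id"
    ),
    species
  ) |>
    dplyr::summarise(slope = coef(lm(y10 ~ site_mean))[2])
  expect_equal(f_ln$slope, unname(f_10$slope), tolerance = 1e-8)

  # multiplicative unit change (mg/g -> percent) shifts logs by a constant
  scaled <- dplyr::mutate(sim$data, leaf_n = leaf_n / 10)
  f_scaled <- fit_species_regressions(scaled, "leaf_n")
  expect_equal(f_scaled$slope, f_ln$slope, tolerance = 1e-8)
})

test_that("slope density mode behaves at calibration points", {
  # all slopes equal: mode at that value
  flat <- tibble::tibble(slope = rep(0.7, 50))
  expect_equal(slope_distribution(flat)$mode, 0.7, tolerance = 0.01)

  # symmetric bimodal: mode lands on one of the two peaks
  set.seed(15)
  bi <- tibble::tibble(
    slope = c(rnorm(100, 0, 0.01), rnorm(100, 1, 0.01))
  )
  sd_bi <- slope_distribution(bi)
  expect_true(
    abs(sd_bi$mode - 0) < 0.05 || abs(sd_bi$mode - 1) < 0.05
  )
  # density near-symmetric around 0.5
  dens <- sd_bi$density
  left <- dens$density[dens$slope < 0.5]
  right <- rev(dens$density[dens$slope > 0.5])
  k <- min(length(left), length(right))
  expect_lt(
    max(abs(left[seq_len(k)] - right[seq_len(k)])) / max(dens$density),
    0.05
  )
})

test_that("occurrence ranges use 1-99% interpolated quantiles and normalize", {
  # species occupying sites with means 1..100: q99 - q1 = 99.01 - 1.99
  d <- as_trait_data(tibble::tibble(
    species = "A", site_id = sprintf("s%03d", 1:100),
    leaf_n = 1:100, leaf_p = 1
  ))
  r <- species_ranges(d, "leaf_n")
  expect_equal(r$range_raw, 97.02, tolerance = 1e-10)
  expect_equal(r$range_norm, 1) # occupies every site

  # mean normalization alternative
  r_mean <- species_ranges(d, "leaf_n", normalization = "mean")
  expect_equal(r_mean$range_norm, 97.02 / mean(1:100), tolerance = 1e-10)

  # ranges grow with niche width
  widths <- c(0.2, 0.4, 0.6, 0.8)
  med <- vapply(widths, function(w) {
    sim <- generate_trait_data(trait_sim_config(
      n_species = 40, n_sites = 60,
      occupancy = list(type = "niche", width = w),
      niche_alignment = 1, sigma_species = 0.1, sigma_resid = 0.05,
      seed = 16
    ))
    median(species_ranges(sim$data, "leaf_n")$range_norm)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("range correlations respond to shared occupancy", {
  # same niche windows couple the two traits' ranges
  sim <- generate_trait_data(trait_sim_config(
    n_species = 100, n_sites = 80,
    occupancy = list(type = "niche", width = 0.3),
    niche_alignment = 1, sigma_species = 0.15, sigma_resid = 0.05,
    seed = 18
  ))
  rng <- dplyr::bind_rows(
    species_ranges(sim$data, "leaf_n"),
    species_ranges(sim$data, "leaf_p")
  )
  rc <- range_correlations(rng)
  expect_gt(rc$pearson_r, 0.4)

  # identical ranges give r = 1
  dup <- dplyr::mutate(
    species_ranges(sim$data, "leaf_n"),
    trait = "copy"
  )
  rc1 <- range_correlations(dplyr::bind_rows(
    species_ranges(sim$data, "leaf_n"), dup
  ))
  expect_equal(rc1$pearson_r, 1, tolerance = 1e-12)
})

test_that("species variation decomposition obeys the ANOVA identity", {
  sim <- generate_trait_data(trait_sim_config(
    n_species = 25, n_sites = 20, sigma_species = 0.4,
    slope_dist = list(type = "normal", mean = 1, sd = 0.2), seed = 19
  ))
  dec <- species_variation_decomposition(sim$data, "leaf_n")
  expect_equal(dec$r2_across + dec$r2_within, 1, tolerance = 1e-8)
  expect_equal(
    dec$r2_across,
    anova_between_share(log(sim$data$leaf_n), sim$data$species),
    tolerance = 1e-10
  )

  # zero within-species variance: all across
  cfg0 <- trait_sim_config(
    n_species = 10, n_sites = 8,
    slope_dist = list(type = "point", value = 0), sigma_resid = 0, seed = 20
  )
  d0 <- generate_trait_data(cfg0)$data
  dec0 <- species_variation_decomposition(d0, "leaf_n")
  expect_equal(dec0$r2_across, 1, tolerance = 1e-10)
  expect_true(dec0$within_degenerate)
  expect_equal(dec0$r2_within, 0)

  # all species share one mean (only within variance): all within
  d1r <- normalize_to_global_mean(sim$data, "leaf_n")
  dec1r <- species_variation_decomposition(d1r, "leaf_n", scale = "raw")
  expect_true(dec1r$across_degenerate)
  expect_equal(dec1r$r2_across, 0)
  expect_equal(dec1r$r2_within, 1, tolerance = 1e-10)

  expect_error(
    species_variation_decomposition(
      dplyr::mutate(d0, species = "one"), "leaf_n"
    ),
    "at least 2 species"
  )
})

test_that("tga wrapper ties the pieces together with tidier methods", {
  sim <- generate_trait_data(trait_sim_config(
    n_species = 40, n_sites = 30,
    slope_dist = list(type = "normal", mean = 1, sd = 0.2),
    sigma_species = 0.4, sigma_resid = 0.05, seed = 22
  ))
  res <- tga(sim$data, traits = c("leaf_n", "leaf_p"))
  expect_s3_class(res, "tga")
  expect_equal(nrow(glance(res)), 2)
  expect_true(all(c("slope_mode", "r2_across") %in% names(glance(res))))
  expect_equal(sort(unique(tidy(res)$trait)), c("leaf_n", "leaf_p"))
  expect_equal(nrow(res$range_correlations), 1)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
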