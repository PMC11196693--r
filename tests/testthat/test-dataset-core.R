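test_that("read_trait_data fills N:P, enforces schema, and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,site_id,leaf_n,leaf_p",
    "A,s1,20,1", "A,s2,20,1", "B,s1,20,1"
  ), path)
  d <- read_trait_data(path)
  expect_equal(d$np_ratio, rep(20, 3))
  expect_equal(nrow(d), 3)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,leaf_n,leaf_p", "A,20,1"), bad)
  expect_error(read_trait_data(bad), "site_id")

  # schema remapping
  mapped <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SpeciesName,site_id,leaf_n,leaf_p", "A,s1,20,1"), mapped)
  expect_equal(
    read_trait_data(mapped, schema = c(species = "SpeciesName"))$species, "A"
  )

  # write/read round trip on a generated fixture
  sim <- generate_trait_data(trait_sim_config(
    n_species = 10, n_sites = 10, seed = 7,
    covariates = cov_spec("e1", 0.2)
  ))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trait_data(sim$data, f)
  back <- read_trait_data(f)
  expect_equal(
    as.data.frame(back[, names(sim$data)]),
    as.data.frame(sim$data),
    tolerance = 1e-12
  )
})

test_that("as_trait_data validates positivity and N:P consistency", {
  expect_error(
    as_trait_data(tibble::tibble(
      species = "A", site_id = "s", leaf_n = -1, leaf_p = 1
    )),
    "strictly positive"
  )
  expect_error(
    as_trait_data(tibble::tibble(
      species = "A", site_id = "s", leaf_n = 20, leaf_p = 1, np_ratio = 25
    )),
    "disagrees"
  )
})

test_that("N:P filter removes ratios strictly above the threshold", {
  d <- as_trait_data(tibble::tibble(
    species = "A", site_id = sprintf("s%d", 1:4),
    leaf_n = c(10, 69.9, 70.0, 70.1), leaf_p = 1
  ))
  out <- filter_np_outliers(d)
  expect_equal(out$np_ratio, c(10, 69.9, 70.0))
  rep <- filter_report(out)
  expect_equal(rep$n_removed, 1L)
  expect_equal(rep$fraction_removed, 0.25)

  # all below threshold: identity
  ok <- filter_np_outliers(d[1:2, ])
  expect_equal(nrow(ok), 2)
  expect_equal(filter_report(ok)$fraction_removed, 0)

  # planted outliers in a large table, fraction checked by direct scan
  set.seed(11)
  big <- as_trait_data(tibble::tibble(
    species = "A", site_id = "s",
    leaf_n = exp(rnorm(10000, log(20), 0.2)), leaf_p = 1
  ))
  big$np_ratio[c(17, 404, 5000, 9999)] <- c(71, 80, 90, 100)
  big$leaf_n <- big$np_ratio * big$leaf_p
  out <- filter_np_outliers(big)
  expect_equal(filter_report(out)$n_removed, sum(big$np_ratio > 70))
  expect_equal(filter_report(out)$fraction_removed, 4 / 10000)
})

test_that("filters are idempotent and N:P-first ordering is a real choice", {
  sim <- generate_trait_data(trait_sim_config(
    n_species = 12, n_sites = 12,
    occupancy = list(type = "fixed", sites_per_species = 6), seed = 3
  ))
  d <- sim$data
  d$np_ratio[1:5] <- 75
  d$leaf_n <- d$np_ratio * d$leaf_p

  strip <- function(x) {
    attr(x, "filter_report") <- NULL
    as.data.frame(x)
  }
  once <- filter_np_outliers(d)
  twice <- filter_np_outliers(once)
  expect_equal(strip(twice), strip(once))
  expect_equal(filter_report(twice)$n_removed, 0L)

  occ_once <- filter_occurrence(d, 3, 3)
  occ_twice <- filter_occurrence(occ_once, 3, 3)
  expect_equal(strip(occ_twice), strip(occ_once))

  # the two filters do not commute in general
  a <- filter_occurrence(filter_np_outliers(d), 3, 3)
  b <- filter_np_outliers(filter_occurrence(d, 3, 3))
  expect_false(identical(a$record_id, b$record_id))
})

test_that("occurrence filter applies both criteria jointly in one pass", {
  d <- crossed_dataset(6, 6)
  kept <- filter_occurrence(d)
  expect_equal(nrow(kept), nrow(d)) # all counts are 6

  # a species alone at its 10 sites fails the site criterion
  lonely <- as_trait_data(tibble::tibble(
    species = "L", site_id = sprintf("x%d", 1:10),
    leaf_n = 20, leaf_p = 1.5
  ))
  both <- dplyr::bind_rows(d, lonely)
  out <- filter_occurrence(both)
  expect_false("L" %in% out$species)

  # brute-force recount of the joint single-pass criteria
  sim <- generate_trait_data(trait_sim_config(
    n_species = 30, n_sites = 25,
    occupancy = list(type = "fixed", sites_per_species = 6), seed = 5
  ))
  out <- filter_occurrence(sim$data, 5, 5)
  occ <- table(sim$data$species, sim$data$site_id) > 0
  good_sp <- rownames(occ)[rowSums(occ) >= 5]
  good_site <- colnames(occ)[colSums(occ) >= 5]
  expect_equal(
    nrow(out),
    sum(sim$data$species %in% good_sp & sim$data$site_id %in% good_site)
  )
  expect_error(
    filter_occurrence(lonely, 5, 5),
    "no species-site pairs survive"
  )
})

test_that("site aggregation matches an independent group-by", {
  d <- as_trait_data(tibble::tibble(
    species = c("A", "B", "C"), site_id = c("s1", "s1", "s2"),
    leaf_n = c(10, 20, 7), leaf_p = c(1, 2, 0.5)
  ))
  agg <- aggregate_sites(d)
  expect_equal(agg$leaf_n[agg$site_id == "s1"], 15)
  expect_equal(agg$leaf_n[agg$site_id == "s2"], 7) # single record site
  expect_equal(agg$n_species, c(2L, 1L))

  sim <- generate_trait_data(trait_sim_config(
    n_species = 20, n_sites = 50,
    occupancy = list(type = "fixed", sites_per_species = 20), seed = 9,
    covariates = cov_spec("e1", 0.3)
  ))
  agg <- aggregate_sites(sim$data)
  oracle <- tapply(sim$data$leaf_n, sim$data$site_id, mean)
  expect_equal(agg$leaf_n, as.numeric(oracle[agg$site_id]), tolerance = 1e-12)
  # equal-record weighting preserves the record-weighted grand mean
  expect_equal(
    sum(agg$leaf_n * agg$n_records) / sum(agg$n_records),
    mean(sim$data$leaf_n),
    tolerance = 1e-12
  )
})

test_that("modified-dataset constructions obey their algebra", {
  toy <- toy_two_species()

  centred <- center_within_species(toy)
  expect_equal(centred$leaf_n, c(-1, 1, 0, 0))

  repl <- replace_with_species_means(toy)
  expect_equal(repl$leaf_n, c(2, 2, 10, 10))
  expect_equal(mean(repl$leaf_n), mean(toy$leaf_n)) # grand mean preserved

  norm <- normalize_to_global_mean(toy)
  expect_equal(norm$leaf_n, c(5, 7, 6, 6)) # x - xbar_i + xbar, xbar = 6
  sp_means <- tapply(norm$leaf_n, norm$species, mean)
  expect_equal(as.numeric(sp_means), rep(mean(toy$leaf_n), 2), tolerance = 1e-10)

  # centering and recentering differ exactly by the grand mean
  expect_equal(norm$leaf_n - centred$leaf_n, rep(mean(toy$leaf_n), 4))

  # ANOVA identity: variance of the within-only data = within SS / N
  sim <- generate_trait_data(trait_sim_config(
    n_species = 15, n_sites = 20, sigma_species = 0.5, seed = 21
  ))
  x <- sim$data$leaf_n
  within_ss <- sum((x - stats::ave(x, sim$data$species))^2)
  norm <- normalize_to_global_mean(sim$data)
  expect_equal(
    sum((norm$leaf_n - mean(norm$leaf_n))^2), within_ss,
    tolerance = 1e-8
  )

  # single-record species centre to exactly zero
  singles <- as_trait_data(tibble::tibble(
    species = c("A", "B"), site_id = "s", leaf_n = c(5, 9), leaf_p = 1
  ))
  expect_equal(center_within_species(singles)$leaf_n, c(0, 0))
})

test_that("log transform is natural log and rejects non-positive values", {
  d <- as_trait_data(tibble::tibble(
    species = "A", site_id = c("s1", "s2"),
    leaf_n = c(exp(1), 1), leaf_p = c(1, 1)
  ))
  out <- log_transform_traits(d, "leaf_n")
  expect_equal(out$leaf_n, c(1, 0))
  d2 <- d
  d2$np_ratio[1] <- 0
  expect_error(log_transform_traits(d2, "np_ratio"), "non-positive")
})

test_that("Yeo-Johnson transform has the closed forms and inverts", {
  x <- c(0, 0.5, 1, 2, 10)
  expect_equal(yeo_johnson(x, lambda = 1)$values, x)
  expect_equal(yeo_johnson(x, lambda = 0)$values, log(x + 1))

  # ML lambda reduces right skew of a lognormal sample
  set.seed(4)
  y <- exp(rnorm(500, 0, 0.8))
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  tr <- yeo_johnson(y)
  expect_lt(abs(skew(tr$values)), abs(skew(y)))

  # inverse recovers the input, including negative values
  z <- c(-3, -0.4, 0, 0.7, 5)
  for (lam in c(-0.5, 0, 0.7, 1, 2)) {
    tr <- yeo_johnson(z, lambda = lam)
    expect_equal(inverse_yeo_johnson(tr), z, tolerance = 1e-8)
  }
})
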