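# Small in-code fixtures shared across tests.

# A toy two-species dataset used by the modified-dataset operations:
# species A has trait values 1 and 3, species B has 10 and 10.
toy_two_species <- function(trait = "leaf_n") {
  d <- tibble::tibble(
    species = c("A", "A", "B", "B"),
    site_id = c("s1", "s2", "s1", "s2"),
    leaf_n = c(1, 3, 10, 10),
    leaf_p = c(1, 1, 1, 1)
  )
  as_trait_data(d)
}

# A balanced crossed dataset: every species at every site, with an optional
# extra numeric column built from independent species and site effects.
crossed_dataset <- function(n_species = 6, n_sites = 6, seed = 1) {
  set.seed(seed)
  d <- tidyr::expand_grid(
    species = sprintf("sp%02d", seq_len(n_species)),
    site_id = sprintf("site%02d", seq_len(n_sites))
  )
  d$leaf_n <- exp(stats::rnorm(nrow(d), log(20), 0.3))
  d$leaf_p <- exp(stats::rnorm(nrow(d), log(1.5), 0.3))
  as_trait_data(d)
}

# Independent one-way ANOVA oracle: between-group SS / total SS, computed
# with base R group means only.
anova_between_share <- function(values, groups) {
  grand <- mean(values)
  group_means <- tapply(values, groups, mean)
  n_g <- tapply(values, groups, length)
  between <- sum(n_g * (group_means[names(n_g)] - grand)^2)
  total <- sum((values - grand)^2)
  between / total
}
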