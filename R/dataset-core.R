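# Core data model: species-by-site leaf trait tables.
#
# A trait dataset is an ordinary tibble with the reserved columns
#   record_id, species, genus, family, site_id, year,
#   leaf_n, leaf_p, np_ratio
# (genus/family/year optional); every other numeric column is treated as an
# environmental covariate. Filters attach a `filter_report` attribute.

RESERVED_COLS <- c(
  "record_id", "species", "genus", "family", "site_id", "year",
  "leaf_n", "leaf_p", "np_ratio"
)
TRAIT_COLS <- c("leaf_n", "leaf_p", "np_ratio")

#' Names of the environmental covariate columns of a trait dataset
#'
#' Every column that is not one of the reserved identity/trait columns
#' (`record_id`, `species`, `genus`, `family`, `site_id`, `year`, `leaf_n`,
#' `leaf_p`, `np_ratio`) is treated as an environmental covariate.
#'
#' @param data A trait dataset tibble.
#' @return Character vector of covariate column names (possibly empty).
#' @export
covariate_names <- function(data) {
  setdiff(names(data), RESERVED_COLS)
}

#' Read a species-by-site leaf trait table from CSV
#'
#' Expects a header row with at least `species`, `site_id`, `leaf_n`, and
#' `leaf_p`; `record_id`, `genus`, `family`, `year`, and `np_ratio` are
#' optional. All remaining numeric columns are kept as environmental
#' covariates. Where `np_ratio` is absent or missing it is filled as
#' `leaf_n / leaf_p`.
#'
#' @param path Path to a UTF-8 CSV file with "." as the decimal separator.
#' @param schema Optional named character vector mapping the file's column
#'   names onto the canonical names, e.g. `c(species = "SpeciesName")`.
#' @return A tibble with one row per trait record.
#' @export
read_trait_data <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("schema maps '", canonical, "' to missing column '", src, "'",
          call. = FALSE
        )
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  mandatory <- c("species", "site_id", "leaf_n", "leaf_p")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "mandatory column(s) missing from input: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (tr in intersect(c("leaf_n", "leaf_p", "np_ratio"), names(raw))) {
    if (!is.numeric(raw[[tr]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[tr]]))) &
        !is.na(raw[[tr]]))
      stop(
        "non-numeric value in trait column '", tr, "' at row ",
        if (length(bad)) bad[1] else NA_integer_,
        call. = FALSE
      )
    }
  }
  as_trait_data(raw)
}

#' Coerce a data frame to a validated trait dataset
#'
#' Fills `np_ratio` from `leaf_n / leaf_p` where missing, adds `record_id`
#' when absent, and checks that concentrations are strictly positive and that
#' any supplied `np_ratio` agrees with `leaf_n / leaf_p` to a relative
#' tolerance of 1e-6.
#'
#' @param data A data frame with at least `species`, `site_id`, `leaf_n`,
#'   `leaf_p`.
#' @return A tibble.
#' @export
as_trait_data <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"record_id" %in% names(data)) {
    data <- dplyr::mutate(data, record_id = paste0("r", dplyr::row_number()))
  }
  if (any(data$leaf_n <= 0, na.rm = TRUE) || any(data$leaf_p <= 0, na.rm = TRUE)) {
    stop("leaf_n and leaf_p must be strictly positive (log scale must exist)",
      call. = FALSE
    )
  }
  implied <- data$leaf_n / data$leaf_p
  if (!"np_ratio" %in% names(data)) {
    data$np_ratio <- implied
  } else {
    miss <- is.na(data$np_ratio)
    data$np_ratio[miss] <- implied[miss]
    both <- !is.na(data$np_ratio) & !is.na(implied)
    rel <- abs(data$np_ratio[both] - implied[both]) / pmax(abs(implied[both]), 1e-300)
    if (any(rel > 1e-6)) {
      stop("np_ratio disagrees with leaf_n/leaf_p beyond relative tolerance 1e-6",
        call. = FALSE
      )
    }
  }
  order_cols <- c(intersect(RESERVED_COLS, names(data)), covariate_names(data))
  data[, order_cols]
}

#' Write a trait dataset to CSV
#'
#' @param data A trait dataset tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_data <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

new_filter_report <- function(rule, n_input, removed_ids) {
  tibble::tibble(
    rule = rule,
    n_input = n_input,
    n_removed = length(removed_ids),
    fraction_removed = length(removed_ids) / n_input,
    removed_ids = list(removed_ids)
  )
}

#' Retrieve the report attached by the most recent filter
#'
#' @param data A tibble returned by [filter_np_outliers()] or
#'   [filter_occurrence()].
#' @return A one-row tibble with columns `rule`, `n_input`, `n_removed`,
#'   `fraction_removed`, and a list-column `removed_ids`, or `NULL` when no
#'   filter has been applied.
#' @export
filter_report <- function(data) {
  attr(data, "filter_report", exact = TRUE)
}

#' Remove records with extreme N:P ratios
#'
#' Drops records whose N:P ratio exceeds `threshold` (strictly greater than;
#' records at exactly the threshold are kept). The default of 70 g N (g P)^-1
#' is the conventional upper plausibility bound for field measurements.
#'
#' @param data A trait dataset tibble with `np_ratio` on all rows.
#' @param threshold Upper bound on N:P; rows with `np_ratio > threshold` are
#'   removed.
#' @return The filtered tibble, with a `filter_report` attribute
#'   (see [filter_report()]).
#' @export
filter_np_outliers <- function(data, threshold = 70) {
  stopifnot(!any(is.na(data$np_ratio)))
  keep <- data$np_ratio <= threshold
  report <- new_filter_report("np_ratio_gt_threshold", nrow(data),
    removed_ids = data$record_id[!keep]
  )
  if (!any(keep)) {
    warning("N:P filter removed every record", call. = FALSE)
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Occurrence filter: well-replicated species at well-sampled sites
#'
#' Keeps records of species recorded at `min_sites_per_species` or more
#' distinct sites, at sites where `min_species_per_site` or more distinct
#' species were sampled. By default both criteria are evaluated on the input
#' dataset and applied jointly in a single pass. With `iterate = TRUE` the
#' pass is repeated until a fixed point, since removing a species can push a
#' site below the species threshold and vice versa.
#'
#' @param data A trait dataset tibble.
#' @param min_sites_per_species Minimum distinct sites a species must occupy.
#' @param min_species_per_site Minimum distinct species a site must host.
#' @param iterate Repeat the joint filter to a fixed point?
#' @return The filtered tibble with a `filter_report` attribute.
#' @export
filter_occurrence <- function(data,
                              min_sites_per_species = 5,
                              min_species_per_site = 5,
                              iterate = FALSE) {
  n_input <- nrow(data)
  current <- data
  repeat {
    species_ok <- current |>
      dplyr::distinct(.data$species, .data$site_id) |>
      dplyr::count(.data$species) |>
      dplyr::filter(.data$n >= min_sites_per_species) |>
      dplyr::pull(.data$species)
    site_ok <- current |>
      dplyr::distinct(.data$species, .data$site_id) |>
      dplyr::count(.data$site_id) |>
      dplyr::filter(.data$n >= min_species_per_site) |>
      dplyr::pull(.data$site_id)
    keep <- current$species %in% species_ok & current$site_id %in% site_ok
    nxt <- current[keep, , drop = FALSE]
    if (!iterate || nrow(nxt) == nrow(current)) {
      current <- nxt
      break
    }
    current <- nxt
  }
  if (nrow(current) == 0) {
    stop("no species-site pairs survive the occurrence filter", call. = FALSE)
  }
  report <- new_filter_report(
    if (iterate) "occurrence_fixed_point" else "occurrence_single_pass",
    n_input,
    removed_ids = setdiff(data$record_id, current$record_id)
  )
  attr(current, "filter_report") <- report
  current
}

#' Aggregate a trait dataset to site level
#'
#' Computes per-site means of the traits and all covariates. The default
#' weighting gives every record equal weight (one record, one vote), which is
#' the community-weighted mean attainable without abundance data; the
#' `"species_mean"` weighting first averages within species at each site.
#'
#' @param data A trait dataset tibble.
#' @param weighting `"record"` (default) or `"species_mean"`.
#' @return A tibble with one row per site: `site_id`, `n_records`,
#'   `n_species`, then per-trait and per-covariate means.
#' @export
aggregate_sites <- function(data, weighting = c("record", "species_mean")) {
  weighting <- match.arg(weighting)
  value_cols <- c(intersect(TRAIT_COLS, names(data)), covariate_names(data))
  base <- data
  if (weighting == "species_mean") {
    base <- data |>
      dplyr::group_by(.data$site_id, .data$species) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(value_cols), ~ mean(.x, na.rm = TRUE)),
        .groups = "drop"
      )
  }
  counts <- data |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      .groups = "drop"
    )
  means <- base |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(value_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  out <- dplyr::left_join(counts, means, by = "site_id")
  nan_cols <- vapply(out[value_cols], function(x) any(is.nan(x)), logical(1))
  if (any(nan_cols)) {
    warning(
      "all-missing values at some site for: ",
      paste(value_cols[nan_cols], collapse = ", "),
      call. = FALSE
    )
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::all_of(value_cols),
      ~ ifelse(is.nan(.x), NA_real_, .x)
    ))
  }
  out
}

#' Summarise a trait dataset by species
#'
#' @param data A trait dataset tibble.
#' @return One row per species: `species`, `n_records`, `n_sites`, and
#'   per-trait means.
#' @export
summarise_species <- function(data) {
  trait_cols <- intersect(TRAIT_COLS, names(data))
  data |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_sites = dplyr::n_distinct(.data$site_id),
      dplyr::across(dplyr::all_of(trait_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Remove across-species variation by centering each species on zero
#'
#' Subtracts the species mean from every trait value, so the result contains
#' only within-species variation. Covariates are untouched.
#'
#' @param data A trait dataset tibble.
#' @param traits Trait columns to modify.
#' @return The modified tibble.
#' @export
center_within_species <- function(data, traits = TRAIT_COLS) {
  traits <- intersect(traits, names(data))
  data |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(traits),
      ~ .x - mean(.x, na.rm = TRUE)
    )) |>
    dplyr::ungroup()
}

#' Remove within-species variation by replacing values with species means
#'
#' @param data A trait dataset tibble.
#' @param traits Trait columns to modify.
#' @return The modified tibble; values are constant within species and the
#'   grand mean is preserved.
#' @export
replace_with_species_means <- function(data, traits = TRAIT_COLS) {
  traits <- intersect(traits, names(data))
  data |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(traits),
      ~ mean(.x, na.rm = TRUE) + 0 * .x
    )) |>
    dplyr::ungroup()
}

#' Keep only within-species variation, recentered on the global mean
#'
#' Each value x_ik of species i becomes x_ik - x_bar_i + x_bar, so every
#' species' mean equals the input grand mean and only within-species
#' variation remains.
#'
#' @param data A trait dataset tibble.
#' @param traits Trait columns to modify.
#' @return The modified tibble.
#' @export
normalize_to_global_mean <- function(data, traits = TRAIT_COLS) {
  traits <- intersect(traits, names(data))
  for (tr in traits) {
    grand <- mean(data[[tr]], na.rm = TRUE)
    data <- data |>
      dplyr::group_by(.data$species) |>
      dplyr::mutate(!!tr := .data[[tr]] - mean(.data[[tr]], na.rm = TRUE) + grand) |>
      dplyr::ungroup()
  }
  data
}

#' Natural-log transform trait columns
#'
#' @param data A trait dataset tibble with strictly positive trait values.
#' @param traits Trait columns to transform.
#' @return The tibble with traits replaced by their natural logarithms.
#' @export
log_transform_traits <- function(data, traits = TRAIT_COLS) {
  traits <- intersect(traits, names(data))
  for (tr in traits) {
    bad <- which(!is.na(data[[tr]]) & data[[tr]] <= 0)
    if (length(bad) > 0) {
      stop(
        "non-positive value in '", tr, "' at record ",
        data$record_id[bad[1]], "; log transform undefined",
        call. = FALSE
      )
    }
  }
  dplyr::mutate(data, dplyr::across(dplyr::all_of(traits), log))
}

#' Yeo-Johnson power transform with maximum-likelihood lambda
#'
#' Estimates the transform exponent by maximum likelihood (via
#' [car::powerTransform()]) and applies the monotone Yeo-Johnson mapping,
#' which behaves like a Box-Cox power for positive values and is defined for
#' all reals.
#'
#' @param values Numeric vector.
#' @param lambda Optional fixed exponent; estimated when `NULL`.
#' @return A list of class `"yj_transform"` with elements `lambda`,
#'   `values` (transformed series), and `input`.
#' @export
yeo_johnson <- function(values, lambda = NULL) {
  stopifnot(is.numeric(values))
  if (is.null(lambda)) {
    lambda <- unname(stats::coef(
      car::powerTransform(values, family = "yjPower")
    ))
  }
  structure(
    list(lambda = lambda, values = yj_apply(values, lambda), input = values),
    class = "yj_transform"
  )
}

yj_apply <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log(x[pos] + 1)
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log(-x[neg] + 1)
  }
  out[is.na(x)] <- NA_real_
  out
}

yj_inverse <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- !is.na(y) & y >= 0
  neg <- !is.na(y) & y < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- (lambda * y[pos] + 1)^(1 / lambda) - 1
  } else {
    out[pos] <- exp(y[pos]) - 1
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- 1 - (1 - (2 - lambda) * y[neg])^(1 / (2 - lambda))
  } else {
    out[neg] <- 1 - exp(-y[neg])
  }
  out[is.na(y)] <- NA_real_
  out
}

#' Invert a Yeo-Johnson transform
#'
#' @param object A `"yj_transform"` object from [yeo_johnson()], or a numeric
#'   vector (then `lambda` is required).
#' @param lambda Exponent, when `object` is a plain numeric vector.
#' @return Numeric vector on the original scale.
#' @export
inverse_yeo_johnson <- function(object, lambda = NULL) {
  if (inherits(object, "yj_transform")) {
    return(yj_inverse(object$values, object$lambda))
  }
  stopifnot(!is.null(lambda))
  yj_inverse(object, lambda)
}
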