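# End-to-end orchestration: ingest or simulate, filter, select features,
# compare models, run the trait gradient analysis, and render a report.

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest (CSV path, trait tibble, or a generator scenario
#' name / config), N:P outlier filter, random-forest recursive feature
#' elimination per trait on the site-aggregated data, model comparison
#' across the three data versions, occurrence filter, trait gradient
#' analysis with the species-variation decomposition, and the shared-effect
#' decomposition. A stage that fails flags its cell and the run continues;
#' the report records per-stage status.
#'
#' @param input A CSV path, a trait dataset tibble, a scenario name for
#'   [make_scenario()], or a [trait_sim_config()].
#' @param traits Trait columns to analyze.
#' @param np_threshold N:P plausibility bound (see [filter_np_outliers()]).
#' @param min_sites_per_species,min_species_per_site Occurrence thresholds.
#' @param rfe_tol Final-set tolerance for [select_final_set()].
#' @param n_trees,n_folds Random-forest and cross-validation settings.
#' @param seed Master seed; expanded into per-stage streams.
#' @param skip Character vector of stages to skip, among
#'   `"feature_selection"`, `"model_comparison"`, `"tga"`,
#'   `"shared_effects"`.
#' @return An object of class `"run_report"`: a list with `status` (tibble
#'   of stage outcomes), `filters`, `selected` (per-trait predictor sets),
#'   `rfe_paths`, `model_grid`, `tga`, `shared_effects`, `truth` (for
#'   simulated input), `seed`, and `ok` (all stages succeeded).
#' @export
run_pipeline <- function(input,
                         traits = c("leaf_n", "leaf_p", "np_ratio"),
                         np_threshold = 70,
                         min_sites_per_species = 5,
                         min_species_per_site = 5,
                         rfe_tol = 0.01,
                         n_trees = 500,
                         n_folds = 5,
                         seed = 1L,
                         skip = character()) {
  seed <- as.integer(seed)
  status <- list()
  note <- function(stage, ok, detail = NA_character_) {
    status[[length(status) + 1]] <<- tibble::tibble(
      stage = stage, ok = ok, detail = detail
    )
  }

  truth <- NULL
  if (is.character(input) && length(input) == 1 && !file.exists(input)) {
    input <- make_scenario(input, seed = seed)
  }
  if (inherits(input, "trait_sim_config")) {
    sim <- generate_trait_data(input)
    data <- sim$data
    truth <- sim$truth
    note("ingest", TRUE, "simulated")
  } else if (is.character(input)) {
    data <- read_trait_data(input)
    note("ingest", TRUE, input)
  } else {
    data <- as_trait_data(input)
    note("ingest", TRUE, "in-memory")
  }

  data <- filter_np_outliers(data, threshold = np_threshold)
  np_report <- filter_report(data)
  note("np_filter", TRUE, sprintf("removed %d", np_report$n_removed))

  covs <- covariate_names(data)
  selected <- NULL
  rfe_paths <- NULL
  if (!"feature_selection" %in% skip && length(covs) >= 2) {
    site <- aggregate_sites(log_transform_traits(data, traits))
    rfe_paths <- purrr::map(stats::setNames(traits, traits), function(tr) {
      rfe(site, tr, covs,
        n_folds = n_folds, n_trees = n_trees,
        seed = seed + 11L
      )
    })
    selected <- purrr::map(rfe_paths, select_final_set, tol = rfe_tol)
    note("feature_selection", TRUE)
  } else {
    selected <- purrr::map(stats::setNames(traits, traits), ~covs)
    note(
      "feature_selection", TRUE,
      if ("feature_selection" %in% skip) "skipped" else "too few covariates"
    )
  }

  model_grid <- NULL
  if (!"model_comparison" %in% skip && length(covs) >= 1) {
    model_grid <- purrr::map_dfr(traits, function(tr) {
      compare_models(data, selected[[tr]],
        traits = tr, n_folds = n_folds,
        n_trees = n_trees, seed = seed + 23L
      )
    })
    failed <- sum(is.na(model_grid$value))
    note("model_comparison", failed == 0, sprintf("%d cell(s) flagged", failed))
  } else {
    note("model_comparison", TRUE, "skipped")
  }

  tga_res <- NULL
  if (!"tga" %in% skip) {
    tga_res <- tryCatch(
      tga(data, traits,
        min_sites_per_species = min_sites_per_species,
        min_species_per_site = min_species_per_site
      ),
      error = function(e) e
    )
    if (inherits(tga_res, "error")) {
      note("tga", FALSE, conditionMessage(tga_res))
      tga_res <- NULL
    } else {
      note("tga", TRUE)
    }
  } else {
    note("tga", TRUE, "skipped")
  }

  shared <- NULL
  if (!"shared_effects" %in% skip) {
    shared <- purrr::map_dfr(traits, function(tr) {
      dplyr::mutate(
        shared_effects(log_transform_traits(data, tr), tr),
        trait = tr, .before = 1
      )
    })
    note("shared_effects", TRUE)
  } else {
    note("shared_effects", TRUE, "skipped")
  }

  status <- dplyr::bind_rows(status)
  structure(
    list(
      status = status,
      filters = np_report,
      selected = selected,
      rfe_paths = rfe_paths,
      model_grid = model_grid,
      tga = tga_res,
      shared_effects = shared,
      truth = truth,
      traits = traits,
      seed = seed,
      ok = all(status$ok)
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  print(x$status)
  if (!is.null(x$tga)) print(glance(x$tga))
  invisible(x)
}

#' Write a human-readable summary and figures for a pipeline run
#'
#' Purely presentational: serializes the tables the pipeline already
#' computed (no new numbers) as CSV/JSON plus a text summary, and renders
#' the elimination-path, model-grid, and slope-density figures when the
#' corresponding stages ran.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(p) paths[length(paths) + 1] <<- p

  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    sprintf("pipeline run, seed %d", report$seed),
    sprintf(
      "stages: %s",
      paste(sprintf(
        "%s[%s]", report$status$stage,
        ifelse(report$status$ok, "ok", "FAILED")
      ), collapse = " ")
    )
  )
  if (is.null(report$model_grid)) {
    lines <- c(lines, "no models fitted")
  }
  if (!is.null(report$tga)) {
    g <- glance(report$tga)
    lines <- c(lines, utils::capture.output(print(as.data.frame(g))))
  }
  writeLines(lines, summary_path)
  put(summary_path)

  jsonlite::write_json(
    list(
      seed = report$seed,
      selected = report$selected,
      filters = dplyr::select(report$filters, -"removed_ids")
    ),
    file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  put(file.path(dir, "run_report.json"))

  if (!is.null(report$model_grid)) {
    readr::write_csv(report$model_grid, file.path(dir, "model_grid.csv"))
    put(file.path(dir, "model_grid.csv"))
    p <- plot_model_grid(report$model_grid)
    ggplot2::ggsave(file.path(dir, "model_grid.png"), p,
      width = 8, height = 5, dpi = 120
    )
    put(file.path(dir, "model_grid.png"))
  }
  if (!is.null(report$rfe_paths)) {
    for (tr in names(report$rfe_paths)) {
      readr::write_csv(
        report$rfe_paths[[tr]]$steps,
        file.path(dir, sprintf("rfe_path_%s.csv", tr))
      )
      put(file.path(dir, sprintf("rfe_path_%s.csv", tr)))
      p <- autoplot(report$rfe_paths[[tr]])
      ggplot2::ggsave(file.path(dir, sprintf("rfe_path_%s.png", tr)), p,
        width = 7, height = 5, dpi = 120
      )
      put(file.path(dir, sprintf("rfe_path_%s.png", tr)))
    }
  }
  if (!is.null(report$tga)) {
    readr::write_csv(tidy(report$tga), file.path(dir, "tga_fits.csv"))
    put(file.path(dir, "tga_fits.csv"))
    jsonlite::write_json(
      list(
        summary = glance(report$tga),
        range_correlations = report$tga$range_correlations
      ),
      file.path(dir, "tga_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    put(file.path(dir, "tga_summary.json"))
    p <- autoplot(report$tga)
    ggplot2::ggsave(file.path(dir, "tga_slopes.png"), p,
      width = 7, height = 5, dpi = 120
    )
    put(file.path(dir, "tga_slopes.png"))
  }
  if (!is.null(report$shared_effects)) {
    readr::write_csv(
      report$shared_effects,
      file.path(dir, "shared_effects.csv")
    )
    put(file.path(dir, "shared_effects.csv"))
  }
  invisible(paths)
}
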