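# Figure helpers. Purely presentational; no new numbers are computed here.

#' Plot a recursive-feature-elimination path
#'
#' Horizontal bars of the cross-validated R-squared at each set size, with
#' the predictor eliminated at that step on the axis: the last predictor to
#' be removed (the most important) sits at the bottom.
#'
#' @param object An [rfe()] path.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rfe_path
#' @export
autoplot.rfe_path <- function(object, ...) {
  steps <- object$steps |>
    dplyr::mutate(
      label = ifelse(is.na(.data$eliminated), "(last retained)",
        .data$eliminated
      ),
      label = factor(.data$label, levels = rev(.data$label))
    )
  ggplot2::ggplot(
    steps,
    ggplot2::aes(x = .data$cv_r2, y = .data$label)
  ) +
    ggplot2::geom_col(fill = "#4d7c4d") +
    ggplot2::labs(
      x = expression("cross-validated" ~ R^2),
      y = "predictor eliminated at this step",
      title = "Recursive feature elimination"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison grid
#'
#' Bar panel per data version showing the explained-variance metric of each
#' model (cross-validated R-squared for RF/LM, marginal R-squared and ICC
#' for the mixed model).
#'
#' @param grid A [compare_models()] tibble.
#' @return A ggplot object.
#' @export
plot_model_grid <- function(grid) {
  d <- dplyr::filter(grid, !is.na(.data$value))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$trait, y = .data$value,
      fill = paste(.data$model, .data$metric)
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$data_version) +
    ggplot2::labs(
      x = NULL, y = "proportion of variation explained", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the plasticity-slope distribution of a trait gradient analysis
#'
#' Kernel densities of the species-specific gradient slopes per trait, with
#' reference lines at 0 (fixed stoichiometry) and 1 (full plasticity).
#'
#' @param object A [tga()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tga
#' @export
autoplot.tga <- function(object, ...) {
  dens <- purrr::imap_dfr(
    object$densities,
    ~ dplyr::mutate(.x, trait = .y)
  )
  ggplot2::ggplot(
    dens,
    ggplot2::aes(x = .data$slope, y = .data$density, colour = .data$trait)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dashed") +
    ggplot2::labs(
      x = "species-specific gradient slope", y = "density",
      title = "Distribution of plasticity slopes"
    ) +
    ggplot2::theme_minimal()
}
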