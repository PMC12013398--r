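#' Plot a production heatmap
#'
#' Tile plot of the volumetric antibody synthesis rate over the dilution
#' rate x biomass grid, annotated with the limiting nutrient(s) of each
#' feasible cell; infeasible (washout) cells are blank.
#'
#' @param object an `igg_heatmap` from [scan_grid()].
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.igg_heatmap <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    label = purrr::map_chr(.data$limiting, function(l) {
      paste(sub("_[a-z]$", "", l), collapse = "\n")
    }))
  xlab <- if (df$X_units[1] == "cells") {
    expression(Biomass ~ (10^6 ~ cells ~ mL^-1))
  } else {
    expression(Biomass ~ (gDW ~ L^-1))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$X),
                                   y = factor(.data$D))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$igg_volumetric_rate),
                       color = "grey80") +
    ggplot2::geom_text(data = df[df$feasible, ],
                       ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = expression(IgG ~ (mu*M ~ h^-1))) +
    ggplot2::labs(x = xlab, y = expression(Dilution ~ rate ~ (h^-1))) +
    ggplot2::theme_minimal()
}

#' Plot a medium-uncertainty production curve
#'
#' @param object an `uncertainty_curve` from [uncertainty_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.uncertainty_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = 100 * .data$u,
                               y = .data$igg_volumetric_rate)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Medium uncertainty (%)",
                  y = expression(Max ~ IgG ~ production ~ (mu*M ~ h^-1))) +
    ggplot2::theme_minimal()
}

#' Plot an optimized medium against the nominal one
#'
#' Side-by-side bars of nominal and optimized nutrient concentrations.
#'
#' @param object an `optimized_medium` from [minimize_medium_cost()] or
#'   [minimize_total_inflow()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.optimized_medium <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("original_mM", "optimized_mM"),
                        names_to = "medium", values_to = "mM") |>
    dplyr::mutate(medium = ifelse(.data$medium == "original_mM",
                                  "nominal", "optimized"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nutrient, y = .data$mM,
                                   fill = .data$medium)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Concentration (mM)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a nutrient classification
#'
#' Production after single-nutrient removal, colored by class.
#'
#' @param object a `nutrient_classification` from [classify_nutrients()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nutrient_classification <- function(object, ...) {
  df <- tibble::as_tibble(object)
  base <- attr(object, "baseline_flux")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$nutrient,
                                                      .data$production),
                                   y = .data$production,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = base, linetype = 2) +
    ggplot2::labs(x = NULL,
                  y = expression(IgG ~ flux ~ after ~ removal ~
                                   (mmol ~ gDW^-1 ~ h^-1)),
                  fill = NULL) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
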