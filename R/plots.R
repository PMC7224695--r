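# ggplot2 visualizations for the main result types.

#' NMDS ordination plot
#'
#' Scatter of the first two ordination axes, optionally colored by clade.
#'
#' @param object An `nmds_result`.
#' @param clades Optional tibble `species`, `clade`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmds_result <- function(object, clades = NULL, ...) {
  df <- object$points
  if (!is.null(clades)) {
    df <- dplyr::left_join(df, clades, by = "species")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::labs(
      subtitle = sprintf("Kruskal stress-1 = %.3f", object$stress)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(clades)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$clade), size = 2.5)
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
}

#' D-statistic null-distribution plot
#'
#' Histograms of the permutation (random) and Brownian-threshold null sums
#' of sister-clade differences, with the observed value marked.
#'
#' @param object A `d_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.d_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(d = object$d_random, null = "random (D = 1)"),
    tibble::tibble(d = object$d_brownian, null = "Brownian (D = 0)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$d, fill = .data$null)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::geom_vline(xintercept = object$d_obs, linetype = 2) +
    ggplot2::labs(
      x = "sum of sister-clade differences",
      subtitle = sprintf("D = %.3f  (P[D=0] = %.3g, P[D=1] = %.3g)",
                         object$D, object$p_d0, object$p_d1)
    ) +
    ggplot2::theme_minimal()
}

#' Within-class profile heat map
#'
#' Species-by-compound tile plot of within-class percentages, faceted by
#' compound class; zero cells (apparent absence) are drawn dark.
#'
#' @param profiles A [within_class_percentages()] tibble.
#' @param species_order Optional species ordering (e.g. tree tip order).
#' @return A ggplot.
#' @export
plot_profile_heatmap <- function(profiles, species_order = NULL) {
  df <- profiles
  if (!is.null(species_order)) {
    df$species <- factor(df$species, levels = species_order)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$compound, .data$species,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$class),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% of class total") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
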