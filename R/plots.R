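# ggplot2 visualisations of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname thickness_grid
#' @param object A `thickness_map`.
#' @param ... Unused.
#' @export
autoplot.thickness_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, fill = .data$thickness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "thickness (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (nm)", y = "y (nm)",
      title = sprintf(
        "%s thickness, mean %.2f nm",
        attr(object, "boundary"), mean(object$thickness)
      )
    )
}

#' @rdname msd_lateral
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ns)", y = expression(MSD ~ (nm^2)))
}

#' @rdname arrhenius
#' @param object An `arrhenius_fit`.
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, inv_T = 1000 / .data$temperature)
  ggplot2::ggplot(d, ggplot2::aes(.data$inv_T, log(.data$value))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = expression(1000 / T ~ (K^-1)), y = "ln(rate)",
      title = sprintf("E[a] = %.2f kcal/mol", object$Ea)
    )
}

#' @rdname neighbor_enrichment
#' @param object An `enrichment_matrix`.
#' @param ... Unused.
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$neighbor, .data$center,
    fill = .data$enrichment
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$enrichment))) +
    ggplot2::scale_fill_gradient2(midpoint = 1) +
    ggplot2::labs(x = "neighbour class", y = "center class")
}

#' @rdname cluster_size_distribution
#' @param object A `cluster_distribution`.
#' @param ... Unused.
#' @export
autoplot.cluster_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$size), .data$n_clusters)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster size (molecules)", y = "clusters")
}

#' Plot a metric against temperature with its linear fit
#'
#' @param fit A `temperature_fit` from [fit_vs_temperature()].
#' @return A ggplot object.
#' @export
plot_temperature_fit <- function(fit) {
  ggplot2::ggplot(fit$data, ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(
      x = "T (K)", y = "value",
      title = sprintf("slope %.4g per K, R^2 = %.3f", fit$slope, fit$r_squared)
    )
}
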