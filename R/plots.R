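# ggplot2 quick-look plots for the main result types.

#' Plot an RMSD time series
#'
#' @param data Tibble from [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$time_ps / 1000, .data$rmsd)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a per-atom fluctuation profile
#'
#' @param data Tibble from [rmsf()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(seq_along(.data$rmsf), .data$rmsf)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "atom (selection order)", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of a PCA result
#'
#' @param object An `md_pca` object.
#' @param n_modes Leading modes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.md_pca <- function(object, n_modes = 20, ...) {
  d <- utils::head(tidy(object), n_modes)
  ggplot2::ggplot(d, ggplot2::aes(.data$mode, 100 * .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance (%)") +
    ggplot2::theme_minimal()
}

#' Free-energy landscape heat map
#'
#' @param object A `fel_grid` from [fel_2d()].
#' @param max_G Cap for the colour scale, k_B T.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fel_grid <- function(object, max_G = NULL, ...) {
  d <- tidy(object)
  d <- d[is.finite(d$G), ]
  if (!is.null(max_G)) d$G <- pmin(d$G, max_G)
  ggplot2::ggplot(d, ggplot2::aes(.data$pc1, .data$pc2, fill = .data$G)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "G (kT)") +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)") +
    ggplot2::theme_minimal()
}

#' Groove-width profile plot
#'
#' @param profiles Output of [profile_over_trajectory()].
#' @return A ggplot object (major and minor groove means with SD ribbons).
#' @export
plot_grooves <- function(profiles) {
  g <- profiles$grooves
  d <- bind_rows(
    tibble(level = g$level, groove = "major", mean = g$major_mean, sd = g$major_sd),
    tibble(level = g$level, groove = "minor", mean = g$minor_mean, sd = g$minor_sd)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$mean, colour = .data$groove)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$groove),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bp level", y = "groove width (Å)") +
    ggplot2::theme_minimal()
}
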