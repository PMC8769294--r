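#' Plot an absorbance image
#'
#' Raster view of per-pixel optical density with physical axes in
#' micrometres.
#'
#' @param object An [absorbance_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.absorbance_image <- function(object, ...) {
  px <- object$pixel_size
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$od <- as.vector(t(object$pixels))[
    (df$row - 1) * ncol(object$pixels) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col * px, y = .data$row * px,
                                   fill = .data$od)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "OD") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell dye content
#'
#' The central diagnostic view of the method: the distribution of
#' per-cell dye content (fmol/cell by default), optionally split by
#' treatment or overlaid with a classification threshold.
#'
#' @param cells Per-cell tibble from [run_strategy()] or
#'   [measure_cells()]; a `role` or `treatment` column, if present,
#'   colors the histogram.
#' @param unit Column to plot: `"moles_fmol"` (default) or
#'   `"molarity_mmol_per_L"`.
#' @param threshold Optional threshold to draw as a vertical line.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_cell_histogram <- function(cells, unit = "moles_fmol",
                                threshold = NULL, bins = 40) {
  if (!unit %in% names(cells))
    .stop_input(sprintf("column '%s' not found in `cells`", unit))
  grp <- intersect(c("role", "treatment"), names(cells))
  lab <- if (unit == "moles_fmol") "dye content (fmol/cell)"
         else "intracellular molarity (mmol/L)"
  p <- if (length(grp) > 0) {
    ggplot2::ggplot(cells, ggplot2::aes(x = .data[[unit]],
                                        fill = .data[[grp[1]]])) +
      ggplot2::geom_histogram(bins = bins, alpha = 0.7,
                              position = "identity")
  } else {
    ggplot2::ggplot(cells, ggplot2::aes(x = .data[[unit]])) +
      ggplot2::geom_histogram(bins = bins, fill = "steelblue")
  }
  if (!is.null(threshold))
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(threshold),
                                 linetype = "dashed")
  p + ggplot2::labs(x = lab, y = "cells") + ggplot2::theme_minimal()
}

#' Plot a classification result
#'
#' Per-cell dye-content histogram colored by the live/dead call, with
#' the threshold marked.
#'
#' @param object A [classify_cells()] result.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_result <- function(object, bins = 40, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$status)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(live = "#2c7fb8",
                                          dead = "#d7301f")) +
    ggplot2::labs(x = "dye content per cell",
                  y = "cells",
                  subtitle = sprintf("%.1f%% dead (threshold %.3g, %s)",
                                     object$percent_dead, object$threshold,
                                     object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' Absorbance against concentration x path length, with the fitted
#' molar absorption coefficient as a line through the origin.
#'
#' @param object An [fit_epsilon()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epsilon_fit <- function(object, ...) {
  df <- object$records
  df$cl <- df$concentration_mol_per_L * .const$mol_per_L_to_mol_per_m3 *
    df$path_length_m
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cl, y = .data$absorbance)) +
    ggplot2::geom_abline(slope = object$epsilon_mean, intercept = 0,
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration × path length (mol/m²)",
                  y = "absorbance (OD)",
                  subtitle = sprintf("ε = %.0f ± %.0f m²/mol",
                                     object$epsilon_mean, object$epsilon_sd)) +
    ggplot2::theme_minimal()
}
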