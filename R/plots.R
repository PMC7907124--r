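#' Heat map of an anomaly confidence map
#'
#' @param object An [score_map()] result.
#' @param ... Unused.
#' @return A ggplot raster with (0, 0) top-left; unscored pixels are
#'   blank.
#' @method autoplot anomaly_map
#' @export
autoplot.anomaly_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$confidence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "anomaly\nconfidence")
}

#' Integrated-intensity heat map of a spectral map
#'
#' @param object A [spectral_map()].
#' @param ... Unused.
#' @method autoplot spectral_map
#' @export
autoplot.spectral_map <- function(object, ...) {
  rc <- pixel_coords(object)
  df <- tibble::tibble(
    row = rc$row, col = rc$col,
    integrated = ifelse(object$valid, rowSums(object$intensity), NA_real_)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$integrated)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "integrated\nintensity")
}

#' Line plot of one or more spectra
#'
#' @param spectra Long tibble with `wavenumber_cm1`, an intensity
#'   column (`corrected` preferred over `intensity`), and optionally a
#'   `group` column mapped to colour.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra) {
  ycol <- if ("corrected" %in% names(spectra)) "corrected" else "intensity"
  p <- ggplot2::ggplot(spectra,
                       ggplot2::aes(x = .data$wavenumber_cm1,
                                    y = .data[[ycol]]))
  if ("group" %in% names(spectra)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "Raman shift (1/cm)", y = "intensity")
}

#' Volcano plot of differential metabolite results
#'
#' Points coloured by metabolite class, with dashed confidence limits
#' at the fold-change threshold and significance level.
#'
#' @param volcano Tibble from [volcano_table()].
#' @return A ggplot.
#' @export
plot_volcano <- function(volcano) {
  fc <- volcano$fc_threshold[1]
  alpha <- volcano$alpha[1]
  ggplot2::ggplot(volcano, ggplot2::aes(x = .data$log2fc,
                                        y = .data$neg_log10_p,
                                        colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-fc, fc), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value",
                  colour = "class")
}
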