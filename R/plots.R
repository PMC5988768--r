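#' Boxplots of recovered BRC by grade and imaging plane
#'
#' Mirrors the published result figure: one panel per imaging
#' configuration, recovered retardation gradient by degeneration grade.
#'
#' @param object A `brc_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brc_study
#' @export
autoplot.brc_study <- function(object, ...) {
  df <- dplyr::mutate(object$samples,
                      config = factor(.data$config, levels = psoct_configs()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$brc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~config) +
    ggplot2::labs(x = "Degeneration grade",
                  y = "Retardation gradient (rad/mm)") +
    ggplot2::theme_bw()
}

#' Display a phase or intensity image
#'
#' @param object A `phase_image` or `intensity_image`.
#' @param ... Unused.
#' @return A ggplot raster of the image (depth down the y axis).
#' @method autoplot phase_image
#' @export
autoplot.phase_image <- function(object, ...) {
  plot_image(object$values, "Retardation (rad)")
}

#' @rdname autoplot.phase_image
#' @method autoplot intensity_image
#' @export
autoplot.intensity_image <- function(object, ...) {
  plot_image(intensity_db(object), "Intensity (dB)")
}

plot_image <- function(values, fill_label) {
  df <- tidyr::expand_grid(depth = seq_len(nrow(values)),
                           lateral = seq_len(ncol(values)))
  df$value <- as.vector(values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lateral, y = .data$depth,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = fill_label) +
    ggplot2::labs(x = "A-scan", y = "Axial pixel") +
    ggplot2::theme_minimal()
}

#' Phase profile at the analysis column: raw, averaged and smoothed
#'
#' Reproduces the published intermediate-product view: the single-column
#' phase profile, the 10-A-scan lateral average, and the running-average
#' smoothed profile between the detected surface and the maximum depth.
#'
#' @param pair A `bscan_pair`.
#' @param center_ascan Analysis column index.
#' @param settings A [pipeline_settings()].
#' @return A ggplot object.
#' @export
plot_phase_profile <- function(pair, center_ascan,
                               settings = pipeline_settings()) {
  phase <- compute_retardation(pair)
  intensity <- compute_reflectivity(pair)
  raw <- phase$values[, center_ascan]
  averaged <- extract_profile(phase, center_ascan, settings)
  int_profile <- extract_profile(intensity, center_ascan, settings)
  surface <- detect_surface(int_profile, settings)
  max_depth <- find_max_depth(int_profile, surface, settings)
  sm <- rep(NA_real_, length(raw))
  sm[surface:max_depth] <- smooth_profile(averaged[surface:max_depth], settings)
  df <- tibble::tibble(
    pixel = rep(seq_along(raw), 3),
    phase = c(raw, averaged, sm),
    series = rep(c("original", "averaged", "smoothed"), each = length(raw))
  )
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$phase)),
                  ggplot2::aes(x = .data$pixel, y = .data$phase,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Axial pixel", y = "Retardation (rad)", colour = NULL) +
    ggplot2::theme_bw()
}
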