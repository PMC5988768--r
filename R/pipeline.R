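#' Settings for the retardation-gradient (BRC) pipeline
#'
#' @param window_ascans Width of the lateral averaging window in A-scans
#'   (default 10, i.e. a 200 um window at 20 um lateral pixels).
#' @param smooth_window Width (axial pixels, odd) of the running average
#'   applied to the phase profile. Default 15.
#' @param surface_threshold Surface detection: first pixel exceeding this
#'   fraction of the profile maximum. Default 0.5.
#' @param depth_threshold Maximum imaging depth: deepest pixel whose local
#'   mean intensity still exceeds this fraction of the intensity at the
#'   surface. Default 0.05.
#' @param depth_mean_window Width (pixels) of the small running mean used by
#'   the depth threshold. Default 5.
#' @param refractive_index Tissue group index used to calibrate depth from
#'   air to tissue. Default 1.36 (bovine cartilage).
#' @param axial_pixel_air Axial sampling in air (um/pixel). Default 5.
#' @param n_bscans Number of adjacent B-scans aggregated per sample.
#'   Default 5.
#' @return An object of class `pipeline_settings`.
#' @export
pipeline_settings <- function(window_ascans = 10L, smooth_window = 15L,
                              surface_threshold = 0.5, depth_threshold = 0.05,
                              depth_mean_window = 5L, refractive_index = 1.36,
                              axial_pixel_air = 5, n_bscans = 5L) {
  if (window_ascans < 1) stop_psoct("window_ascans must be >= 1", "psoct_invalid_params")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop_psoct("smooth_window must be odd and >= 1", "psoct_invalid_params")
  }
  if (surface_threshold <= 0 || surface_threshold >= 1 ||
      depth_threshold <= 0 || depth_threshold >= 1) {
    stop_psoct("thresholds must lie strictly between 0 and 1", "psoct_invalid_params")
  }
  if (refractive_index < 1) stop_psoct("refractive_index must be >= 1", "psoct_invalid_params")
  structure(
    list(window_ascans = as.integer(window_ascans),
         smooth_window = as.integer(smooth_window),
         surface_threshold = surface_threshold,
         depth_threshold = depth_threshold,
         depth_mean_window = as.integer(depth_mean_window),
         refractive_index = refractive_index,
         axial_pixel_air = axial_pixel_air,
         n_bscans = as.integer(n_bscans)),
    class = "pipeline_settings"
  )
}

#' Tissue depth per axial pixel
#'
#' The axial pixel spacing is defined in air; inside the tissue the same
#' optical path corresponds to `axial_pixel_air / refractive_index` of
#' physical depth.
#'
#' @param settings A [pipeline_settings()].
#' @return Millimetres of tissue per axial pixel.
#' @examples
#' depth_per_pixel(pipeline_settings()) # 5 um / 1.36 = 3.676e-3 mm
#' @export
depth_per_pixel <- function(settings = pipeline_settings()) {
  (settings$axial_pixel_air / 1000) / settings$refractive_index
}

#' Detect the tissue surface in an intensity profile
#'
#' Returns the first axial index (top-down) at which the intensity exceeds
#' `surface_threshold` times the profile maximum.
#'
#' @param intensity_column Nonnegative intensity profile (one column, or the
#'   lateral mean over the analysis window).
#' @param settings A [pipeline_settings()].
#' @return Integer axial index.
#' @export
detect_surface <- function(intensity_column, settings = pipeline_settings()) {
  if (length(intensity_column) == 0) {
    stop_psoct("empty intensity profile", "psoct_no_surface")
  }
  m <- max(intensity_column)
  idx <- which(intensity_column > settings$surface_threshold * m)
  if (m <= 0 || length(idx) == 0) {
    stop_psoct("no pixel exceeds the surface threshold", "psoct_no_surface")
  }
  idx[1]
}

# centred running mean with the window shrunk symmetrically at the edges;
# output has the same length as the input
running_mean <- function(x, window) {
  n <- length(x)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  (cs[i + hh + 1L] - cs[i - hh]) / (2 * hh + 1)
}

#' Maximum usable imaging depth in an intensity profile
#'
#' Returns the deepest axial index below the surface at which a small
#' running mean of the intensity still exceeds `depth_threshold` times the
#' intensity at the surface.
#'
#' @inheritParams detect_surface
#' @param surface Axial surface index from [detect_surface()].
#' @return Integer axial index, always greater than `surface`.
#' @export
find_max_depth <- function(intensity_column, surface,
                           settings = pipeline_settings()) {
  n <- length(intensity_column)
  if (surface < 1 || surface >= n) {
    stop_psoct("surface index out of range", "psoct_insufficient_depth")
  }
  ref <- intensity_column[surface]
  sm <- running_mean(intensity_column[(surface + 1):n], settings$depth_mean_window)
  ok <- which(sm >= settings$depth_threshold * ref)
  if (length(ok) == 0) {
    stop_psoct("signal falls below the depth threshold immediately below the surface",
               "psoct_insufficient_depth")
  }
  surface + max(ok)
}

#' Laterally averaged phase profile around the analysis A-scan
#'
#' Mean of the per-pixel retardation over a window of `window_ascans`
#' columns centred on `center_ascan` (the published 200 um window), per
#' axial pixel. The window is clipped at the image edges with a warning.
#'
#' @param phase A `phase_image` (or `intensity_image`; any object with a
#'   `values` matrix).
#' @param center_ascan Lateral column index.
#' @param settings A [pipeline_settings()].
#' @return Numeric profile, one value per axial pixel.
#' @export
extract_profile <- function(phase, center_ascan,
                            settings = pipeline_settings()) {
  v <- phase$values
  nx <- ncol(v)
  if (center_ascan < 1 || center_ascan > nx) {
    stop_psoct("center_ascan outside the image", "psoct_range_error")
  }
  w <- settings$window_ascans
  lo <- center_ascan - (w - 1L) %/% 2L
  hi <- lo + w - 1L
  if (lo < 1 || hi > nx) {
    rlang::warn("A-scan window clipped at the image edge")
    lo <- max(1L, lo); hi <- min(nx, hi)
  }
  rowMeans(v[, lo:hi, drop = FALSE])
}

#' Running-average smoothing of a phase profile
#'
#' Centred moving average of width `smooth_window`; at the profile ends the
#' window shrinks symmetrically, so the output has the same length and the
#' endpoints are preserved.
#'
#' @param profile Numeric phase profile (radians per axial pixel).
#' @param settings A [pipeline_settings()].
#' @return Smoothed profile of the same length.
#' @export
smooth_profile <- function(profile, settings = pipeline_settings()) {
  if (length(profile) < settings$smooth_window) {
    stop_psoct("profile shorter than the smoothing window", "psoct_degenerate_input")
  }
  running_mean(profile, settings$smooth_window)
}

#' Cumulative absolute phase change per unit tissue depth
#'
#' The retardation gradient (birefringence coefficient): the sum of the
#' absolute pixel-to-pixel phase changes of the smoothed, folded profile
#' over the evaluated depth range, divided by the physical tissue depth the
#' profile spans (number of increments times [depth_per_pixel()], so an
#' unfolded ramp of slope `a` rad/pixel yields exactly
#' `a / depth_per_pixel()`). The sum is taken on the folded data exactly as
#' measured -- no
#' unwrapping -- which preserves the absolute increments everywhere except
#' at the single turning pixel of each fold.
#'
#' @param smoothed Smoothed phase profile covering the full A-scan depth.
#' @param surface Axial surface index.
#' @param max_depth Deepest evaluated axial index (inclusive).
#' @param settings A [pipeline_settings()].
#' @return Retardation gradient (rad/mm), >= 0.
#' @export
cumulative_gradient <- function(smoothed, surface, max_depth,
                                settings = pipeline_settings()) {
  if (max_depth <= surface) {
    stop_psoct("max_depth must exceed surface", "psoct_degenerate_input")
  }
  seg <- smoothed[surface:max_depth]
  if (length(seg) < 2 || anyNA(seg)) {
    stop_psoct("fewer than 2 valid pixels in the evaluated range",
               "psoct_degenerate_input")
  }
  sum(abs(diff(seg))) / ((length(seg) - 1) * depth_per_pixel(settings))
}

#' Retardation gradient of one sample from a B-scan stack
#'
#' Runs the full published procedure on each B-scan of a volume at one
#' lateral analysis position: reconstruct intensity and phase, average a
#' 10-A-scan window, detect the surface, threshold the maximum imaging
#' depth, smooth the phase profile between the two with a running average,
#' and accumulate the absolute phase change per unit tissue depth. The
#' sample's BRC is the arithmetic mean over the adjacent B-scans.
#'
#' @param volume A `psoct_volume` (list of `bscan_pair`s).
#' @param center_ascan Lateral analysis column; `NULL` uses the column
#'   stored by the study driver or the image centre.
#' @param settings A [pipeline_settings()].
#' @return An object of class `brc_result`: fields `brc` (rad/mm),
#'   `per_bscan`, `center_ascan`, `surface_index`, `depth_index`,
#'   `settings`, plus the simulation truth if present. Has [tidy()] and
#'   [glance()] methods.
#' @export
compute_sample_brc <- function(volume, center_ascan = NULL,
                               settings = pipeline_settings()) {
  pairs <- if (inherits(volume, "bscan_pair")) list(volume) else volume
  if (length(pairs) < 1) stop_psoct("empty volume", "psoct_structural_error")
  if (is.null(center_ascan)) center_ascan <- ceiling(ncol(pairs[[1]]$Av) / 2)

  per <- purrr::imap(pairs, function(pair, b) {
    res <- tryCatch({
      intensity <- compute_reflectivity(pair)
      phase <- compute_retardation(pair)
      int_profile <- extract_profile(intensity, center_ascan, settings)
      phase_profile <- extract_profile(phase, center_ascan, settings)
      surface <- detect_surface(int_profile, settings)
      max_depth <- find_max_depth(int_profile, surface, settings)
      seg <- phase_profile[surface:max_depth]
      smoothed <- smooth_profile(seg, settings)
      full <- phase_profile
      full[surface:max_depth] <- smoothed
      brc <- cumulative_gradient(full, surface, max_depth, settings)
      list(brc = brc, surface = surface, max_depth = max_depth)
    }, psoct_error = function(e) {
      stop_psoct(paste0("B-scan ", b, ": ", conditionMessage(e)), class(e)[1])
    })
    res
  })

  per_bscan <- vapply(per, function(p) p$brc, 1)
  structure(
    list(brc = mean(per_bscan), per_bscan = per_bscan,
         center_ascan = as.integer(center_ascan),
         surface_index = vapply(per, function(p) p$surface, 1L),
         depth_index = vapply(per, function(p) p$max_depth, 1L),
         settings = settings,
         truth_brc = attr(volume, "truth_brc", exact = TRUE),
         grade = attr(volume, "grade", exact = TRUE),
         config = attr(volume, "config", exact = TRUE)),
    class = "brc_result"
  )
}

#' @export
print.brc_result <- function(x, ...) {
  cat(sprintf("<brc_result> BRC %.3f rad/mm over %d B-scans (per-B-scan: %s)\n",
              x$brc, length(x$per_bscan),
              paste(sprintf("%.3f", x$per_bscan), collapse = ", ")))
  if (!is.null(x$truth_brc)) cat(sprintf("  simulation truth: %.3f rad/mm\n", x$truth_brc))
  invisible(x)
}
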