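#' Reflectivity image from a two-channel B-scan pair
#'
#' The relative reflectivity is the per-pixel sum of the squared channel
#' amplitudes, `R(z) = Av(z)^2 + Ah(z)^2` (up to the system's overall
#' proportionality). Invariant under swapping the channels, and -- because
#' the polarisation optics are unitary -- independent of any retardance
#' accumulated above the pixel.
#'
#' @param pair A `bscan_pair` from [simulate_bscan()] or [read_volume()].
#' @return An object of class `intensity_image` with fields `values`
#'   (depth x lateral, >= 0) and `params`.
#' @export
compute_reflectivity <- function(pair) {
  check_pair(pair)
  structure(list(values = pair$Av^2 + pair$Ah^2, params = pair$params),
            class = "intensity_image")
}

#' Retardation image from a two-channel B-scan pair
#'
#' Per-pixel retardation `delta = arctan(Av / Ah)`, which the pi/2 phase
#' wrap confines to [0, pi/2]: `Ah = 0` with `Av > 0` maps to pi/2, and a
#' pixel where both amplitudes are exactly zero (no signal at all) is
#' defined as 0 and flagged in the validity mask rather than raising an
#' error, since above-surface noise-floor pixels are routinely near zero.
#' The output is invariant under rescaling both channels by any positive
#' constant.
#'
#' @param pair A `bscan_pair`.
#' @return An object of class `phase_image` with fields `values` (radians in
#'   [0, pi/2]), `valid` (logical mask, FALSE where both channels are zero)
#'   and `params`.
#' @export
compute_retardation <- function(pair) {
  check_pair(pair)
  if (any(pair$Av < 0) || any(pair$Ah < 0)) {
    stop_psoct("channel amplitudes must be >= 0", "psoct_structural_error")
  }
  valid <- !(pair$Av == 0 & pair$Ah == 0)
  values <- atan2(pair$Av, pair$Ah)
  values[!valid] <- 0
  structure(list(values = values, valid = valid, params = pair$params),
            class = "phase_image")
}

check_pair <- function(pair) {
  if (!inherits(pair, "bscan_pair")) {
    stop_psoct("expected a bscan_pair", "psoct_structural_error")
  }
  if (!identical(dim(pair$Av), dim(pair$Ah))) {
    stop_psoct("channel images must have identical shape", "psoct_structural_error")
  }
  invisible(pair)
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image> %d x %d, range [%.3f, %.3f] rad\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Log-scaled intensity for display
#'
#' Display-only helper: all computation in the pipeline uses linear
#' intensities.
#'
#' @param image An `intensity_image`.
#' @param floor_db Dynamic-range floor (dB).
#' @return A matrix of dB values.
#' @export
intensity_db <- function(image, floor_db = -60) {
  v <- image$values / max(image$values)
  pmax(10 * log10(pmax(v, .Machine$double.xmin)), floor_db)
}
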