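#' Acquisition parameters of the simulated PS-OCT system
#'
#' Defaults follow the swept-source system that motivated the simulator:
#' 1310 nm centre wavelength, 10 um axial resolution in air (sampled at
#' 5 um/pixel, Nyquist), 20 um lateral pixel, 10 mm image width, and 25 um
#' separation between adjacent B-scans. `noise_sigma` scales the
#' multiplicative Rayleigh speckle on the channel amplitudes; the default
#' 0.4 produces a single-A-scan phase SD of ~0.15 rad at the most sensitive
#' operating point, which is what motivates the pipeline's averaging steps.
#'
#' @param wavelength Centre wavelength (nm).
#' @param axial_pixel_air Axial sampling in air (um/pixel).
#' @param axial_resolution_air Axial resolution in air (um).
#' @param lateral_pixel Lateral pixel (um).
#' @param image_width Lateral image width (mm).
#' @param n_depth Number of axial pixels per A-scan.
#' @param n_ascans Number of A-scans per B-scan; `NULL` derives it from
#'   `image_width / lateral_pixel`.
#' @param bscan_separation Separation between adjacent B-scans (um).
#' @param noise_sigma Relative amplitude speckle scale, >= 0 (0 = noiseless).
#' @param noise_floor Relative amplitude of the above-surface noise floor.
#' @return An object of class `acq_params`.
#' @export
acquisition_params <- function(wavelength = 1310, axial_pixel_air = 5,
                               axial_resolution_air = 10, lateral_pixel = 20,
                               image_width = 10, n_depth = 256L,
                               n_ascans = NULL, bscan_separation = 25,
                               noise_sigma = 0.4, noise_floor = 0.01) {
  if (wavelength <= 0 || axial_pixel_air <= 0 || lateral_pixel <= 0 ||
      image_width <= 0 || n_depth < 2 || noise_sigma < 0 || noise_floor < 0) {
    stop_psoct("invalid acquisition parameters", "psoct_invalid_params")
  }
  if (is.null(n_ascans)) n_ascans <- max(1L, round(image_width * 1000 / lateral_pixel))
  if (n_ascans < 1) stop_psoct("n_ascans must be >= 1", "psoct_invalid_params")
  structure(
    list(wavelength = wavelength, axial_pixel_air = axial_pixel_air,
         axial_resolution_air = axial_resolution_air,
         lateral_pixel = lateral_pixel, image_width = image_width,
         n_depth = as.integer(n_depth), n_ascans = as.integer(n_ascans),
         bscan_separation = bscan_separation, noise_sigma = noise_sigma,
         noise_floor = noise_floor),
    class = "acq_params"
  )
}

#' Convert a tissue birefringence to the measured retardation gradient
#'
#' Round-trip convention: the measured retardation of a homogeneous slab is
#' delta(z) = (2 pi / lambda) * 2 * dn * z, so the gradient is
#' `2 pi * 2 * dn / lambda` expressed per millimetre of physical tissue
#' depth. Exact inverse of [dn_for_brc()].
#'
#' @param dn Dimensionless birefringence, >= 0.
#' @param wavelength Centre wavelength (nm). Default 1310.
#' @return Retardation gradient (rad/mm).
#' @export
brc_for_dn <- function(dn, wavelength = 1310) {
  lambda_mm <- wavelength * 1e-6
  4 * pi * dn / lambda_mm
}

# unit-mean Rayleigh draws (coherent-imaging amplitude speckle)
rayleigh_unit <- function(n) {
  sqrt(2 / pi) * sqrt(-2 * log(runif(n)))
}

# lateral positions (mm, block coordinates) of the image columns, centred on
# the block centre
lateral_positions <- function(tissue, params) {
  xc <- tissue$geometry$block_width / 2
  dx <- params$lateral_pixel / 1000
  xc - params$image_width / 2 + (seq_len(params$n_ascans) - 0.5) * dx
}

# core renderer: two-channel amplitudes for a set of lateral positions.
# Assumes the optic axis is depth-constant within each column (true for all
# generated tissue models; checked), which lets the accumulated layer stack
# collapse to a single retarder and the whole image render as vectorised
# closed-form Jones algebra. Equivalence with explicit per-voxel matrix
# products is covered by tests.
render_columns <- function(tissue, x, params, noisy = TRUE) {
  n <- tissue$refractive_index
  dz_air <- params$axial_pixel_air / 1000        # mm
  dz_tis <- dz_air / n
  z <- (seq_len(params$n_depth) - 0.5) * dz_air  # image depth (air), mm

  if (any(x < min(tissue$lateral_grid) | x > max(tissue$lateral_grid))) {
    stop_psoct("lateral position outside the tissue block", "psoct_range_error")
  }
  surf <- approx(tissue$lateral_grid, tissue$surface_height, xout = x)$y
  jx <- vapply(x, function(xi) which.min(abs(tissue$lateral_grid - xi)), 1L)

  axis_cols <- tissue$axis_map[, jx, drop = FALSE]
  if (any(abs(sweep(axis_cols, 2, axis_cols[1, ])) > 1e-12)) {
    stop_psoct("render_columns requires a depth-constant optic axis per column",
               "psoct_invalid_geometry")
  }

  nz <- params$n_depth; nx <- length(x)
  tdep <- outer(z, surf, "-") / n                # tissue depth (mm), <0 above surface
  below <- tdep > 0 & tdep <= tissue$thickness
  tclamp <- pmin(pmax(tdep, 0), tissue$thickness)

  dn_px <- matrix(0, nz, nx)
  for (k in seq_len(nx)) {
    dn_px[, k] <- approx(tissue$depth_grid, tissue$dn_map[, jx[k]], xout = tclamp[, k])$y
  }
  dn_px[!below] <- 0

  coef <- 4 * pi / (params$wavelength * 1e-6)    # rad per (dn * mm)
  delta <- apply(dn_px * dz_tis, 2, cumsum) * coef
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = nz)

  amp <- channel_amplitudes(as.vector(delta),
                            rep(axis_cols[1, ], each = nz))
  scatter <- matrix(0, nz, nx)
  scatter[below] <- approx(tissue$depth_grid, tissue$scatter_profile,
                           xout = tclamp[below])$y
  Av <- matrix(amp$Av, nz, nx) * scatter
  Ah <- matrix(amp$Ah, nz, nx) * scatter

  if (noisy && params$noise_sigma > 0) {
    s <- params$noise_sigma
    nb <- sum(below)
    Av[below] <- Av[below] * ((1 - s) + s * rayleigh_unit(nb))
    Ah[below] <- Ah[below] * ((1 - s) + s * rayleigh_unit(nb))
    na <- sum(!below)
    Av[!below] <- params$noise_floor * rayleigh_unit(na)
    Ah[!below] <- params$noise_floor * rayleigh_unit(na)
  } else {
    Av[!below] <- params$noise_floor / sqrt(2)
    Ah[!below] <- params$noise_floor / sqrt(2)
  }
  list(Av = Av, Ah = Ah, surface = surf)
}

#' Simulate a single A-scan
#'
#' Renders the two orthogonal channel amplitude profiles at one lateral
#' position: below the local surface the accumulated round-trip retardance
#' from the birefringence map is applied to the circularly polarised input
#' and the channel amplitudes are the backscatter profile times the Jones
#' projections, with multiplicative speckle; pixels above the surface carry
#' the noise floor only.
#'
#' @param tissue A [make_tissue()] model.
#' @param lateral_pos Lateral position (mm, block coordinates).
#' @param params An [acquisition_params()].
#' @param seed Integer seed.
#' @return A list with numeric vectors `Av`, `Ah` (length `params$n_depth`).
#' @export
simulate_ascan <- function(tissue, lateral_pos, params = acquisition_params(),
                           seed = 1L) {
  withr::local_seed(derive_seed(seed))
  out <- render_columns(tissue, lateral_pos, params, noisy = TRUE)
  list(Av = out$Av[, 1], Ah = out$Ah[, 1])
}

new_bscan_pair <- function(Av, Ah, params, tissue, lateral = NULL) {
  structure(
    list(Av = Av, Ah = Ah, params = params,
         lateral = lateral,
         truth_brc = tissue$truth_brc, grade = tissue$grade,
         config = tissue$config),
    class = "bscan_pair"
  )
}

#' @export
print.bscan_pair <- function(x, ...) {
  cat(sprintf("<bscan_pair> %d x %d  (%s %s, truth BRC %.3f rad/mm)\n",
              nrow(x$Av), ncol(x$Av),
              x$grade %||% "?", x$config %||% "?", x$truth_brc %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one B-scan pair
#'
#' @inheritParams simulate_ascan
#' @return A `bscan_pair`: co-registered vertical/horizontal channel
#'   amplitude images (depth x lateral) with the acquisition parameters and
#'   the source model's ground truth attached.
#' @export
simulate_bscan <- function(tissue, params = acquisition_params(), seed = 1L) {
  withr::local_seed(derive_seed(seed))
  x <- lateral_positions(tissue, params)
  out <- render_columns(tissue, x, params, noisy = TRUE)
  new_bscan_pair(out$Av, out$Ah, params, tissue, lateral = x)
}

#' Simulate a stack of adjacent B-scans
#'
#' Renders `n_bscans` co-registered B-scan pairs at the configured
#' out-of-plane separation. Generated tissue models are uniform in the
#' out-of-plane direction, so adjacent B-scans differ only by their speckle
#' realisation (each B-scan gets an independent, deterministically derived
#' seed).
#'
#' @inheritParams simulate_ascan
#' @param n_bscans Number of adjacent B-scans. Default 5.
#' @return An object of class `psoct_volume`: a list of `bscan_pair`s with
#'   the source tissue's truth attached.
#' @export
simulate_volume <- function(tissue, params = acquisition_params(),
                            n_bscans = 5L, seed = 1L) {
  if (n_bscans < 1) stop_psoct("n_bscans must be >= 1", "psoct_invalid_params")
  pairs <- purrr::map(seq_len(n_bscans), function(b) {
    simulate_bscan(tissue, params, seed = derive_seed(seed, 0L, b))
  })
  structure(pairs, class = "psoct_volume",
            truth_brc = tissue$truth_brc, grade = tissue$grade,
            config = tissue$config)
}

#' Default analysis column for a simulated volume
#'
#' The published analysis selects the A-scan manually at roughly the same
#' location on each image; the simulator replaces the operator with an
#' explicit default at the bulge shoulder (channel edge + 0.25 mm) for the
#' indented configuration, and the image centre for laterally uniform
#' configurations.
#'
#' @param tissue A [make_tissue()] model.
#' @param params An [acquisition_params()].
#' @return Integer column index.
#' @export
default_center_ascan <- function(tissue, params = acquisition_params()) {
  xc <- tissue$geometry$block_width / 2
  x_eval <- if (identical(tissue$config, "XZ_indented")) {
    shoulder_position(tissue$geometry, xc)
  } else {
    xc
  }
  x <- lateral_positions(tissue, params)
  which.min(abs(x - x_eval))
}
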