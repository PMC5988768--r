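# Shared fixtures: everything is generated in code at test time.

# scaled acquisition: narrower image (fewer A-scans) for speed; axial
# sampling, depth and all physics identical to the defaults
acq_scaled <- function(noise_sigma = 0.4, image_width = 3, ...) {
  acquisition_params(noise_sigma = noise_sigma, image_width = image_width, ...)
}

# a single-row preset with zero between-sample SD so truth_brc is exact
fixed_preset <- function(brc, config = "XZ_nonindented", grade = "G0") {
  p <- grade_presets(config = config, grade = grade)
  p$brc_mean <- brc
  p$brc_sd <- 0
  p
}

# noiseless homogeneous-slab volume with known truth
slab_volume <- function(brc, n_bscans = 1, seed = 1,
                        params = acq_scaled(noise_sigma = 0, image_width = 1)) {
  tissue <- make_tissue(fixed_preset(brc), seed = seed)
  list(
    tissue = tissue,
    params = params,
    volume = simulate_volume(tissue, params, n_bscans = n_bscans, seed = seed)
  )
}

# hand-built B-scan pair from raw matrices (reconstruction unit tests)
raw_pair <- function(Av, Ah) {
  structure(list(Av = Av, Ah = Ah, params = NULL),
            class = "bscan_pair")
}

# independent moving-average oracle: plain loop, shrinking symmetric window
ma_oracle <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  sapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    mean(x[(i - hh):(i + hh)])
  })
}

# closed-form folded retardation ramp for a homogeneous slab rendered by the
# simulator: per-pixel measured retardation below the surface
folded_ramp_oracle <- function(tissue, params, column_x) {
  dz_air <- params$axial_pixel_air / 1000
  z <- (seq_len(params$n_depth) - 0.5) * dz_air
  surf <- approx(tissue$lateral_grid, tissue$surface_height, xout = column_x)$y
  tdep <- (z - surf) / tissue$refractive_index
  below <- tdep > 0
  dn <- tissue$dn_map[1, which.min(abs(tissue$lateral_grid - column_x))]
  coef <- 4 * pi / (params$wavelength * 1e-6)
  delta <- cumsum(ifelse(below, dn * dz_air / tissue$refractive_index, 0)) * coef
  fold <- function(d) { d <- d %% pi; ifelse(d > pi / 2, pi - d, d) }
  list(delta = fold(delta), below = below)
}
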