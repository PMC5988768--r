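#' Channel-indentation geometry
#'
#' Geometry of the creep-loading channel indentation: a flat indenter with a
#' 1 mm channel gap is pressed onto the cartilage block so the tissue bulges
#' up into the gap while the flanks are compressed (mean axial creep strain
#' ~56%). The bulge height is not reported for the original experiment and
#' defaults to a plausible fraction of the compressed thickness.
#'
#' @param channel_gap Width of the unindented bulge region (mm). Default 1.
#' @param strain Axial compressive creep strain under the indenter, in (0, 1).
#'   Default 0.56.
#' @param bulge_height Height of the central surface bulge above the indented
#'   flanks (mm). Default 0.25.
#' @param block_width Lateral extent of the cartilage block (mm). Default 10.
#' @return An object of class `indentation_geometry`.
#' @export
indentation_geometry <- function(channel_gap = 1, strain = 0.56,
                                 bulge_height = 0.25, block_width = 10) {
  if (channel_gap <= 0 || bulge_height < 0 || block_width <= 0) {
    stop_psoct("channel_gap and block_width must be > 0; bulge_height >= 0",
               "psoct_invalid_geometry")
  }
  if (strain <= 0 || strain >= 1) {
    stop_psoct("strain must lie strictly between 0 and 1", "psoct_invalid_geometry")
  }
  structure(
    list(channel_gap = channel_gap, strain = strain,
         bulge_height = bulge_height, block_width = block_width),
    class = "indentation_geometry"
  )
}

#' Convert a target retardation gradient to a tissue birefringence
#'
#' Inverse of [brc_for_dn()] under the round-trip retardation convention
#' delta(z) = (2 pi / lambda) * 2 * dn * z: the measured folded phase ramp of
#' a homogeneous slab with the returned `dn` has slope `target_brc` per
#' millimetre of physical tissue depth.
#'
#' @param target_brc Target retardation gradient (rad/mm), >= 0.
#' @param wavelength Centre wavelength (nm). Default 1310.
#' @return Dimensionless birefringence `dn`.
#' @examples
#' dn_for_brc(3.0) # ~3.13e-4 at 1310 nm
#' brc_for_dn(dn_for_brc(3.0)) # 3.0
#' @export
dn_for_brc <- function(target_brc, wavelength = 1310) {
  if (any(target_brc < 0)) {
    stop_psoct("target_brc must be >= 0", "psoct_domain_error")
  }
  lambda_mm <- wavelength * 1e-6
  target_brc * lambda_mm / (4 * pi)
}

# lateral bump profile of the bulge: raised cosine with compact support of
# width `gap` centred at `center` (mm); 1 at the centre, 0 outside
bulge_profile <- function(x, center, gap) {
  u <- (x - center) / (gap / 2)
  ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
}

# default lateral analysis position: the bulge shoulder, channel edge + 0.25 mm
shoulder_position <- function(geometry, block_center) {
  block_center + geometry$channel_gap / 2 + 0.25
}

#' Generate one ground-truth tissue model
#'
#' Builds a per-sample map of birefringence, optic-axis orientation,
#' backscatter and surface height for one cartilage specimen. The sample's
#' true retardation gradient (`truth_brc`) is drawn from
#' Normal(`brc_mean`, `brc_sd`) truncated at 0 and converted to a
#' birefringence map via [dn_for_brc()], so that an ideal reconstruction at
#' the default analysis position recovers `truth_brc` exactly.
#'
#' Indented-configuration models carry a central surface bulge (the tissue
#' pressed up into the indenter's channel gap), elevated birefringence under
#' the indenter flanks with a laterally asymmetric banding modulation, and
#' reduced birefringence in the free bulge. Non-indented and XY models are
#' laterally uniform with a flat surface. The birefringence map is normalised
#' so that at the default analysis column (bulge shoulder, channel edge +
#' 0.25 mm, or block centre for uniform configurations) the local `dn` equals
#' `dn_for_brc(truth_brc)`.
#'
#' @param preset A single-row preset tibble (one row of [grade_presets()]).
#' @param geometry An [indentation_geometry()].
#' @param sample_index Integer specimen index (used in seed fan-out).
#' @param seed Integer seed; identical (preset, geometry, sample_index, seed)
#'   give bit-identical models.
#' @param thickness Uncompressed cartilage thickness (mm). Default 2.
#' @param air_gap Depth of the uncompressed surface below the image top (mm).
#'   Default 0.2.
#' @param refractive_index Tissue group refractive index. Default 1.36.
#' @param attenuation_depth 1/e depth of the backscatter amplitude (mm of
#'   tissue). Default 1.
#' @param n_depth,n_lateral Model grid size. Defaults 64 x 501.
#' @return An object of class `tissue_model` with fields `dn_map`, `axis_map`
#'   (depth x lateral), `surface_height` (mm below image top, per lateral
#'   position), `lateral_grid`, `depth_grid`, `truth_brc`, `grade`, `config`.
#' @export
make_tissue <- function(preset, geometry = indentation_geometry(),
                        sample_index = 1L, seed = 1L,
                        thickness = 2, air_gap = 0.2,
                        refractive_index = 1.36, attenuation_depth = 1,
                        n_depth = 64L, n_lateral = 501L) {
  validate_preset(preset)
  if (!inherits(geometry, "indentation_geometry")) {
    stop_psoct("geometry must be an indentation_geometry()", "psoct_invalid_geometry")
  }
  if (thickness <= 0 || n_depth < 2 || n_lateral < 2) {
    stop_psoct("thickness must be > 0 and the grid at least 2 x 2",
               "psoct_invalid_geometry")
  }

  withr::local_seed(derive_seed(seed, sample_index))
  truth_brc <- rtruncnorm0(1, preset$brc_mean, preset$brc_sd)
  dn0 <- dn_for_brc(truth_brc)

  xs <- seq(0, geometry$block_width, length.out = n_lateral)
  zs <- seq(0, thickness, length.out = n_depth)
  xc <- geometry$block_width / 2
  indented <- preset$config == "XZ_indented"

  if (indented) {
    bump <- bulge_profile(xs, xc, geometry$channel_gap)
    surface <- air_gap + geometry$bulge_height * (1 - bump)
    x_eval <- shoulder_position(geometry, xc)
    # banding modulation: elevated dn under the flanks, reduced in the free
    # bulge, linear lateral asymmetry; normalised to 1 at the analysis column
    shape <- (1 - 0.6 * bump) *
      (1 + preset$banding_asymmetry * (xs - xc) / (geometry$block_width / 2))
    shape_eval <- (1 - 0.6 * bulge_profile(x_eval, xc, geometry$channel_gap)) *
      (1 + preset$banding_asymmetry * (x_eval - xc) / (geometry$block_width / 2))
    lateral_dn <- pmax(shape / shape_eval, 0) * dn0
  } else {
    surface <- rep(air_gap, n_lateral)
    lateral_dn <- rep(dn0, n_lateral)
  }

  structure(
    list(
      thickness = thickness,
      dn_map = matrix(lateral_dn, nrow = n_depth, ncol = n_lateral, byrow = TRUE),
      axis_map = matrix(pi / 6, nrow = n_depth, ncol = n_lateral),
      surface_height = surface,
      lateral_grid = xs,
      depth_grid = zs,
      scatter_profile = exp(-zs / attenuation_depth),
      attenuation_depth = attenuation_depth,
      refractive_index = refractive_index,
      truth_brc = truth_brc,
      grade = preset$grade,
      config = preset$config,
      geometry = geometry,
      sample_index = as.integer(sample_index),
      seed = as.integer(seed)
    ),
    class = "tissue_model"
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "<tissue_model> %s %s  truth BRC %.3f rad/mm  grid %d x %d  thickness %g mm\n",
    x$grade, x$config, x$truth_brc, nrow(x$dn_map), ncol(x$dn_map), x$thickness
  ))
  invisible(x)
}
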