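#' Jones matrix of a linear retarder
#'
#' Standard Jones operator of a linear retarder with fast-axis orientation
#' `axis` and retardance `retardance`, in the horizontal/vertical field
#' basis: `R(axis) diag(1, exp(i retardance)) R(-axis)`. Unitary up to a
#' global phase; symmetric, so the same matrix describes the reverse pass of
#' a reciprocal double-pass geometry.
#'
#' @param retardance Retardance (radians), in [0, 2 pi).
#' @param axis Fast-axis orientation (radians), in [0, pi).
#' @return A 2 x 2 complex matrix.
#' @examples
#' retarder_matrix(0, 0.3) # identity
#' @export
retarder_matrix <- function(retardance, axis = 0) {
  if (retardance < 0 || retardance >= 2 * pi) {
    stop_psoct("retardance must lie in [0, 2 pi)", "psoct_domain_error")
  }
  if (axis < 0 || axis >= pi) {
    stop_psoct("axis must lie in [0, pi)", "psoct_domain_error")
  }
  c <- cos(axis); s <- sin(axis)
  rot <- matrix(c(c, s, -s, c), 2, 2)
  rot %*% diag(c(1 + 0i, exp(1i * retardance))) %*% t(rot)
}

# quarter-wave plate at 45 degrees: circularises the horizontal input and is
# double-passed in the sample arm
qwp45 <- function() retarder_matrix(pi / 2, pi / 4)

#' Two-channel amplitudes for an accumulated sample retardance
#'
#' Propagates the horizontally polarised source field through the sample arm:
#' quarter-wave plate at 45 deg (circular incidence on the sample), the
#' sample's round-trip Jones operator, and the quarter-wave plate again on
#' return, then splits into the two orthogonal detection channels. Under the
#' round-trip convention the sample operator for accumulated measured
#' retardation `delta` at optic axis `axis` is a retarder of retardance
#' `2 * delta`; the detected channel ratio then satisfies
#' `arctan(Av / Ah) = fold(delta)`, independent of `axis`.
#'
#' @param delta Accumulated retardation(s), radians (vectorised).
#' @param axis Optic-axis orientation (radians), scalar or same length.
#' @return A list with numeric vectors `Av` and `Ah` (unit-energy amplitudes,
#'   `Av^2 + Ah^2 = 1`).
#' @export
channel_amplitudes <- function(delta, axis = 0) {
  n <- max(length(delta), length(axis))
  delta <- rep_len(delta, n); axis <- rep_len(axis, n)
  q <- qwp45()
  # M(axis, 2 delta) entries, vectorised over depth
  e <- exp(2i * delta)
  c2 <- cos(axis)^2; s2 <- sin(axis)^2; cs <- cos(axis) * sin(axis)
  m11 <- c2 + s2 * e; m12 <- cs * (1 - e); m22 <- s2 + c2 * e
  # first column of Q %*% M %*% Q (input field (1, 0))
  n1 <- m11 * q[1, 1] + m12 * q[2, 1]
  n2 <- m12 * q[1, 1] + m22 * q[2, 1]
  e1 <- q[1, 1] * n1 + q[1, 2] * n2
  e2 <- q[2, 1] * n1 + q[2, 2] * n2
  # the cross-polarised return carries sin(delta): label it the V channel so
  # that arctan(Av/Ah) reads the folded retardation
  list(Av = Mod(e1), Ah = Mod(e2))
}

# reference implementation by explicit matrix products (used in tests and for
# depth-varying-axis layer stacks): elements is a list of (retardance, axis)
# one-way layers, traversed in order and back (reciprocal round trip)
jones_round_trip <- function(elements) {
  fwd <- diag(2) + 0i
  for (el in elements) fwd <- retarder_matrix(el$retardance, el$axis) %*% fwd
  # linear retarder matrices in this basis are symmetric, so the return pass
  # through each element is the same matrix in reverse order
  back <- diag(2) + 0i
  for (el in rev(elements)) back <- retarder_matrix(el$retardance, el$axis) %*% back
  q <- qwp45()
  out <- q %*% back %*% fwd %*% q %*% c(1 + 0i, 0i)
  list(Av = Mod(out[1]), Ah = Mod(out[2]))
}

#' Virtual Berek-compensator phase evaluation
#'
#' Reproduces the phase-evaluation experiment in which a calibrated variable
#' retarder (Berek compensator) with settable retardance and optic axis is
#' placed in the sample arm and the measured retardation is compared with the
#' set value. Circular light is propagated through the element (double pass)
#' and the retardation recovered as the arctangent of the channel amplitude
#' ratio, folded into [0 deg, 90 deg] by the pi/2 phase wrap. With no noise
#' the measured value equals the folded set retardation exactly, for every
#' optic-axis setting.
#'
#' @param set_retardation Set retardation (degrees), in [0, 180]. Vectorised.
#' @param set_axis Set optic axis (degrees), in [0, 180]. Vectorised.
#' @param noise_sd Measurement noise SD (degrees) added to the recovered
#'   angle, then re-folded. Default 0.
#' @param seed Optional integer seed for the noise.
#' @return Measured retardation(s) in degrees, in [0, 90].
#' @examples
#' berek_measure(90, 20) # 90
#' berek_measure(120, 45) # folds to 60
#' @export
berek_measure <- function(set_retardation, set_axis, noise_sd = 0, seed = NULL) {
  if (any(set_retardation < 0 | set_retardation > 180)) {
    stop_psoct("set_retardation must lie in [0, 180] degrees", "psoct_domain_error")
  }
  if (any(set_axis < 0 | set_axis > 180)) {
    stop_psoct("set_axis must lie in [0, 180] degrees", "psoct_domain_error")
  }
  n <- max(length(set_retardation), length(set_axis))
  set_retardation <- rep_len(set_retardation, n)
  set_axis <- rep_len(set_axis, n)
  amp <- channel_amplitudes(set_retardation * pi / 180,
                            (set_axis %% 180) * pi / 180)
  meas <- atan2(amp$Av, amp$Ah) * 180 / pi
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    meas <- fold_pi2((meas + rnorm(n, 0, noise_sd)) * pi / 180) * 180 / pi
  }
  meas
}
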