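#' Expected per-fluorophore emission at one polarization angle
#'
#' Plain FPM: the time-averaged cos-squared excitation law with wobble
#' collapsing the modulation towards the isotropic level,
#' \deqn{E = B_0\left[\frac{1-c}{2} + c\cos^2(\alpha-\bar\varphi)\right].}
#' FrExPAN readout frames additionally carry the on-state probability left
#' by the switching pulses at this angle,
#' \deqn{P_{on} = \left(1 - e^{-a\cos^2(\alpha-\bar\varphi)}\right)
#'       e^{-b\sin^2(\alpha-\bar\varphi)},}
#' i.e. an on-switch pulse polarized at \eqn{\alpha} followed by a
#' perpendicular off-switch pulse.  Off-state fluorophores emit nothing.
#'
#' @param field a [populate_dipoles()] field
#' @param alpha excitation polarization angle in \eqn{[0, \pi)}
#' @param mode `"fpm"` or `"frexpan"` (readout frame of the pulse scheme)
#' @param dose_on,dose_off switching doses `a` and `b` (frexpan mode)
#' @return expected photons per fluorophore (vector)
#' @export
expected_emission <- function(field, alpha, mode = c("fpm", "frexpan"),
                              dose_on = 6, dose_off = 3) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha >= pi) stopf("'alpha' must be in [0, pi)")
  phi <- dipole_orientation(field)
  c2 <- cos(alpha - phi)^2
  e <- field$B0 * ((1 - field$c) / 2 + field$c * c2)
  if (mode == "frexpan") {
    p_on <- (1 - exp(-dose_on * c2)) * exp(-dose_off * (1 - c2))
    e <- field$B0 * p_on * ((1 - field$c) / 2 + field$c * c2)
  }
  e * as.numeric(field$on)
}

# Emission during a switch frame: fluorescence driven by the intense
# perpendicular off-switch beam, i.e. the cos^2 law evaluated at
# alpha + pi/2, scaled by the plan's switch_brightness.
switch_emission <- function(field, alpha, switch_brightness) {
  phi <- dipole_orientation(field)
  s2 <- cos(alpha + pi / 2 - phi)^2
  switch_brightness * field$B0 * ((1 - field$c) / 2 + field$c * s2) *
    as.numeric(field$on)
}
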