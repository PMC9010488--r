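#' Lorentzian lineshape
#'
#' Unit-amplitude Lorentzian used for both the direct water saturation line
#' and the creatine amine CEST line: `L(x) = w^2 / (w^2 + x^2)` with
#' half-width-at-half-maximum `w` (ppm).
#'
#' @param x Offset from the line centre, ppm (vectorised).
#' @param width Half width at half maximum, ppm; must be positive.
#' @return Values in (0, 1].
#' @export
lorentzian <- function(x, width) {
  if (any(width <= 0)) abort("Lorentzian `width` must be positive.")
  width^2 / (width^2 + x^2)
}

#' Saturation-efficiency curve for relative B1
#'
#' The effective creatine labelling scales with the local saturation
#' amplitude. The curve `s(b) = b^2 / (b^2 + kappa)` is monotone, bounded and
#' invertible; with `kappa = 1` it satisfies `s(1) = 0.5` and is normalised so
#' that the returned efficiency is 1 at nominal B1 (`b1_rel = 1`).
#'
#' @param b1_rel Relative B1 amplitude (1 = nominal); must be positive.
#' @param kappa Curve shape parameter.
#' @return Normalised efficiency, `s(b)/s(1)`; equals 1 at `b1_rel = 1`.
#' @export
saturation_efficiency <- function(b1_rel, kappa = 1) {
  if (any(b1_rel <= 0)) abort("`b1_rel` must be positive.")
  raw <- b1_rel^2 / (b1_rel^2 + kappa)
  raw / (1 / (1 + kappa))
}

default_pools <- function() {
  list(
    water_width_ppm = 1.0,   # direct-saturation HWHM at 3 uT, 500 ms
    water_depth = 0.85,      # water line depth (Z at centre = 0.15)
    cr_center_ppm = 1.8,     # creatine amine resonance
    cr_width_ppm = 0.8,      # exchange-broadened CEST line HWHM
    wassr_width_ppm = 0.3,   # low-power water line for WASSR
    wassr_depth = 0.8
  )
}

#' Two-pool z-spectrum forward model
#'
#' Analytic z-spectrum of a water pool (direct saturation, centred at the
#' voxel's B0 shift) plus a creatine amine pool at `cr_center_ppm` downfield
#' of water, each a Lorentzian:
#' `Z(dw) = 1 - d_w L_w(dw - b0) - s(b1) A L_cr(dw - b0 - cr_center)`,
#' clipped to \[0, 1\]. `A` is the creatine pool amplitude (fraction of the
#' unsaturated signal removed at the creatine centre under nominal B1) and
#' `s(b1)` the normalised [saturation_efficiency()].
#'
#' @param offset_ppm Saturation offset(s) relative to water, ppm.
#' @param cr_amplitude Creatine pool amplitude, signal fraction (>= 0).
#' @param b0_ppm Voxel B0 shift of the water centre, ppm.
#' @param b1_rel Voxel relative B1 (> 0).
#' @param water_width_ppm,water_depth Water line HWHM and depth.
#' @param cr_center_ppm,cr_width_ppm Creatine line centre and HWHM.
#' @return Signal fractions in \[0, 1\], same shape as the broadcast inputs.
#' @examples
#' zspectrum_forward(c(-1.8, 1.8), cr_amplitude = 0.05)
#' @export
zspectrum_forward <- function(offset_ppm, cr_amplitude = 0,
                              b0_ppm = 0, b1_rel = 1,
                              water_width_ppm = default_pools()$water_width_ppm,
                              water_depth = default_pools()$water_depth,
                              cr_center_ppm = default_pools()$cr_center_ppm,
                              cr_width_ppm = default_pools()$cr_width_ppm) {
  if (any(cr_amplitude < 0)) abort("`cr_amplitude` must be non-negative.")
  if (any(b1_rel <= 0)) abort("`b1_rel` must be positive.")
  x <- offset_ppm - b0_ppm
  z <- 1 - water_depth * lorentzian(x, water_width_ppm) -
    saturation_efficiency(b1_rel) * cr_amplitude *
      lorentzian(x - cr_center_ppm, cr_width_ppm)
  if (any(z < -1e-6)) {
    warn("Pool parameters drive the z-spectrum below zero; model validity is doubtful.",
         class = "crcest_model_validity")
  }
  pmin(pmax(z, 0), 1)
}

# Exact asymmetry of the two-pool model at evaluation offset `at_ppm`
# (b0 = 0, b1 = 1), in percent. Includes the creatine tail at the negative
# offset, so calibration round-trips to machine precision.
asym_closed_form <- function(cr_amplitude, at_ppm = 1.8, pools = default_pools()) {
  D <- 1 - pools$water_depth * lorentzian(at_ppm, pools$water_width_ppm)
  L_near <- lorentzian(at_ppm - pools$cr_center_ppm, pools$cr_width_ppm)
  L_far <- lorentzian(at_ppm + pools$cr_center_ppm, pools$cr_width_ppm)
  100 * cr_amplitude * (L_near - L_far) / (D - cr_amplitude * L_far)
}

#' Calibrate the creatine pool amplitude to a target asymmetry
#'
#' Inverts the two-pool forward model so that the MTR asymmetry evaluated at
#' the creatine offset (nominal B0/B1, denominator `Z(-offset)`) equals
#' `target_asym_pct`. Used by the phantom generator to hit prescribed CrCEST
#' levels exactly.
#'
#' @param target_asym_pct Target asymmetry in percent, in \[0, 50).
#' @param at_ppm Evaluation offset, ppm (creatine centre).
#' @param pools Pool parameter list, see `default_pools()`.
#' @return Creatine amplitude (signal fraction).
#' @examples
#' a <- calibrate_cr_amplitude(6.2)
#' @export
calibrate_cr_amplitude <- function(target_asym_pct, at_ppm = 1.8,
                                   pools = default_pools()) {
  if (any(target_asym_pct < 0 | target_asym_pct >= 50)) {
    abort("`target_asym_pct` must lie in [0, 50).",
          class = "crcest_calibration_error")
  }
  t <- target_asym_pct / 100
  D <- 1 - pools$water_depth * lorentzian(at_ppm, pools$water_width_ppm)
  L_near <- lorentzian(at_ppm - pools$cr_center_ppm, pools$cr_width_ppm)
  L_far <- lorentzian(at_ppm + pools$cr_center_ppm, pools$cr_width_ppm)
  amp <- t * D / (L_near - (1 - t) * L_far)
  # amplitude may not push the saturated side below zero
  if (any(D - amp * L_near < 0)) {
    abort("Target asymmetry is unattainable: the saturated side would go negative.",
          class = "crcest_calibration_error")
  }
  amp
}

#' Ground-truth creatine asymmetry time course
#'
#' Free creatine rises with exercise and recovers by oxidative
#' phosphorylation; post-exercise decline is modelled as a single exponential.
#' Baseline frames sit at the resting level; the post-exercise frame at time
#' `t >= t1` (with `t1` the first post-exercise frame time) takes
#' `rest + delta * exp(-(t - t1)/tau)`.
#'
#' @param rest_asym_pct Resting CrCEST, percent asymmetry.
#' @param delta_asym_pct Exercise-induced rise at the first post frame.
#' @param tau_s Recovery time constant, seconds (> 0).
#' @param protocol A [cest_protocol()].
#' @return Tibble with `time_s`, `phase` ("baseline"/"post") and `asym_pct`.
#' @examples
#' cr_time_course(6.2, 8.9, 138, cest_protocol())
#' @export
cr_time_course <- function(rest_asym_pct, delta_asym_pct, tau_s, protocol) {
  if (tau_s <= 0) abort("`tau_s` must be positive.")
  times <- frame_times(protocol)
  post <- times >= 0
  t1 <- min(times[post])
  asym <- ifelse(post,
                 rest_asym_pct + delta_asym_pct * exp(-(times - t1) / tau_s),
                 rest_asym_pct)
  tibble::tibble(
    time_s = times,
    phase = ifelse(post, "post", "baseline"),
    asym_pct = asym
  )
}
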