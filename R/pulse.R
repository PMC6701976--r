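# Gaussian photon pulse model.

#' Define a Gaussian X-ray pulse
#'
#' The temporal profile is `G(t) = (2 Np / T) sqrt(ln 2 / pi)
#' exp(-4 ln(2) (t - t0)^2 / T^2)`, normalised so that its time integral is
#' the total photon count.
#'
#' @param photon_count Total photons in the pulse (e.g. 1e12).
#' @param fwhm Full width at half maximum `T` in fs.
#' @param photon_energy Photon energy in keV (default 8).
#' @param focus_diameter Focal-spot diameter in nm (default 100); photons are
#'   spatially uniform across the focus.
#' @param center_time Pulse centre `t0` in fs (default 0).
#' @return A `pulse_profile` object.
#' @examples
#' p <- pulse_profile(1e12, 5)
#' gaussian_fluence(p, 0)
#' @export
pulse_profile <- function(photon_count, fwhm, photon_energy = 8,
                          focus_diameter = 100, center_time = 0) {
  stopifnot(photon_count > 0, fwhm > 0, photon_energy > 0, focus_diameter > 0)
  structure(list(photon_count = photon_count, fwhm = fwhm,
                 photon_energy = photon_energy,
                 focus_diameter = focus_diameter,
                 center_time = center_time),
            class = "pulse_profile")
}

#' @export
print.pulse_profile <- function(x, ...) {
  cat(sprintf(
    "pulse_profile: %.3g photons, FWHM %g fs, %g keV, %g nm focus, centre %g fs\n",
    x$photon_count, x$fwhm, x$photon_energy, x$focus_diameter, x$center_time))
  invisible(x)
}

#' X-ray wavelength of a pulse
#' @param profile A `pulse_profile` (or photon energy in keV).
#' @return Wavelength in nm.
#' @export
pulse_wavelength <- function(profile) {
  e <- if (inherits(profile, "pulse_profile")) profile$photon_energy else profile
  .const$hc_kev_nm / e
}

#' Focal-spot area of a pulse
#' @param profile A `pulse_profile`.
#' @return Area in nm^2.
#' @export
focal_area <- function(profile) pi * (profile$focus_diameter / 2)^2

#' Instantaneous photon flux of the pulse
#'
#' Evaluates the Gaussian temporal profile at time `t`.
#'
#' @param profile A `pulse_profile`.
#' @param t Time(s) in fs.
#' @return Photons per fs at each `t`.
#' @export
gaussian_fluence <- function(profile, t) {
  T <- profile$fwhm
  tt <- t - profile$center_time
  2 * profile$photon_count / T * sqrt(log(2) / pi) *
    exp(-4 * log(2) * tt^2 / T^2)
}

#' Photon counts in discrete time steps
#'
#' Integrates the Gaussian profile analytically (error-function differences)
#' over consecutive bins of width `dt` starting at `t_start`.
#'
#' @param profile A `pulse_profile`.
#' @param t_start,t_end Window limits in fs (`t_start < t_end`).
#' @param dt Bin width in fs (> 0).
#' @return Numeric vector of photons per bin; bin k covers
#'   `[t_start + (k-1) dt, t_start + k dt]`.
#' @export
discretize_pulse <- function(profile, t_start, t_end, dt) {
  stopifnot(t_start < t_end, dt > 0)
  edges <- seq(t_start, t_end, by = dt)
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  # integral of G from -inf to t
  s <- profile$fwhm / (2 * sqrt(2 * log(2)))  # Gaussian sigma in fs
  cdf <- pnorm(edges, mean = profile$center_time, sd = s)
  profile$photon_count * diff(cdf)
}

# photons per 0.5 fs bin centred on each frame time
.frame_photons <- function(profile, frame_times) {
  dt <- if (length(frame_times) > 1L) frame_times[2] - frame_times[1] else 0.5
  discretize_pulse(profile, frame_times[1] - dt / 2,
                   frame_times[length(frame_times)] + dt / 2, dt)
}

#' Default simulation frame times for a pulse
#'
#' Frames at 0.5 fs spacing spanning the pulse support `[-2T, +2T]` around the
#' pulse centre (clipped to at least +/-10 fs), which carries more than
#' 99.999% of the photons.
#'
#' @param profile A `pulse_profile`.
#' @param dt Frame spacing in fs (default 0.5).
#' @return Numeric vector of frame times in fs.
#' @export
pulse_frame_times <- function(profile, dt = 0.5) {
  half <- max(2 * profile$fwhm, 10)
  seq(profile$center_time - half, profile$center_time + half, by = dt)
}
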