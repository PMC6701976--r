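# Detector geometry, Ewald-sphere pixel map and diffraction patterns.

#' Define a flat square detector
#'
#' Defaults reproduce the reference geometry: 256 x 256 pixels of 33.8 um at
#' 3 mm from the sample with 8 keV photons, spanning resolutions from ~15 A
#' near the central-speckle cutoff to ~1.46 A at the detector corner.  The
#' beam centre sits at the geometric centre of the detector face (between the
#' four central pixels for even pixel counts).
#'
#' @param n_pixels Pixels per side (default 256).
#' @param pixel_size Pixel pitch in um (default 33.8).
#' @param distance Sample-detector distance in mm (default 3).
#' @param photon_energy Photon energy in keV (default 8).
#' @return A `detector_geometry` object.
#' @export
detector_geometry <- function(n_pixels = 256L, pixel_size = 33.8,
                              distance = 3, photon_energy = 8) {
  stopifnot(n_pixels >= 2L, pixel_size > 0, distance > 0, photon_energy > 0)
  structure(list(n_pixels = as.integer(n_pixels), pixel_size = pixel_size,
                 distance = distance, photon_energy = photon_energy),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  qm <- build_qmap(x)
  cat(sprintf(
    "detector_geometry: %d x %d px of %g um at %g mm, %g keV (corner %.2f A)\n",
    x$n_pixels, x$n_pixels, x$pixel_size, x$distance, x$photon_energy,
    10 / max(qm$qmag)))
  invisible(x)
}

#' Map detector pixels to scattering vectors
#'
#' Places every pixel centre on the Ewald sphere: with the unit vector `s`
#' from sample to pixel and the beam direction `s0`, `q = (s - s0)/lambda`, so
#' `|q| = 2 sin(theta_s)/lambda` (crystallographic convention, no 2 pi;
#' resolution is `1/|q|`).  Also evaluates the polarization factor
#' `P = 1 - sin^2(2 theta_s) cos^2(phi)` for horizontal linear polarization
#' and the flat-detector solid angle `dOmega = (p/L)^2 cos^3(2 theta_s)`.
#'
#' @param geom A `detector_geometry`.
#' @return A `qmap`: list of per-pixel vectors (column-major over the
#'   `n x n` grid) `qx`, `qy`, `qz`, `qmag` (nm^-1), `polarization`,
#'   `solid_angle`, `prefactor` (`r_e^2 P dOmega`, nm^2 sr), `pixel_radius`
#'   (distance from beam centre in pixel units) and the generating `geom`.
#' @export
build_qmap <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  n <- geom$n_pixels
  p_mm <- geom$pixel_size / 1000
  off <- (seq_len(n) - (n + 1) / 2) * p_mm          # pixel centres, mm
  X <- matrix(off, n, n)                            # column-major: x varies
  Y <- matrix(off, n, n, byrow = TRUE)
  L <- geom$distance
  w <- sqrt(X^2 + Y^2 + L^2)
  lambda <- pulse_wavelength(geom$photon_energy)    # nm
  qx <- as.vector(X / w) / lambda
  qy <- as.vector(Y / w) / lambda
  qz <- as.vector(L / w - 1) / lambda
  qmag <- sqrt(qx^2 + qy^2 + qz^2)
  cos2t <- as.vector(L / w)
  sin2t <- sqrt(pmax(1 - cos2t^2, 0))
  phi <- atan2(as.vector(Y), as.vector(X))
  pol <- 1 - (sin2t * cos(phi))^2
  dom <- (p_mm / L)^2 * cos2t^3
  structure(list(qx = qx, qy = qy, qz = qz, qmag = qmag,
                 polarization = pol, solid_angle = dom,
                 prefactor = .const$r_e^2 * pol * dom,
                 pixel_radius = as.vector(sqrt(X^2 + Y^2)) / p_mm,
                 geom = geom),
            class = "qmap")
}

.as_qmap <- function(geom) {
  if (inherits(geom, "qmap")) geom else build_qmap(geom)
}

.state_keys <- function(structure) {
  gs <- ground_state_electrons(structure$elements)
  paste(structure$elements, gs$core - structure$core_electrons,
        structure$valence_electrons, sep = ":")
}

.new_pattern <- function(intensity, qmap, frame_time = NA_real_,
                         mode = "instantaneous", fluence = NA_real_) {
  n <- qmap$geom$n_pixels
  structure(list(intensity = matrix(intensity, n, n), qmap = qmap,
                 frame_time = frame_time, mode = mode, fluence = fluence),
            class = "diffraction_pattern")
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  cat(sprintf(
    "diffraction_pattern: %d x %d px, %s, total %.4g photons%s\n",
    nrow(x$intensity), ncol(x$intensity), x$mode, sum(x$intensity),
    if (is.na(x$frame_time)) "" else sprintf(" (t = %g fs)", x$frame_time)))
  invisible(x)
}

#' Instantaneous diffraction pattern of one frame
#'
#' Computes, per pixel, `I = r_e^2 P(q) dOmega F |sum_i f_i(q)
#' exp(2 pi i q . R_i)|^2` in expected-photon units, with ionization-dependent
#' Slater form factors taken from the frame's per-atom electron counts.
#'
#' @param frame An `atomic_structure` whose positions and electron counts
#'   describe the frame.
#' @param geom A `detector_geometry` or prebuilt `qmap`.
#' @param fluence Incident photons per nm^2 in this frame (default 1, i.e. a
#'   unit-fluence pattern).
#' @param cache Optional environment memoising per-state form factors across
#'   calls sharing one geometry.
#' @return A `diffraction_pattern` (field `intensity`: n x n matrix of
#'   expected photons).
#' @export
pattern_instantaneous <- function(frame, geom, fluence = 1, cache = NULL) {
  stopifnot(fluence >= 0)
  qm <- .as_qmap(geom)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  keys <- .state_keys(frame)
  ukeys <- unique(keys)
  fmat <- .ff_matrix(ukeys, qm$qmag, cache)
  amp2 <- .coherent_sum_cpp(qm$qx, qm$qy, qm$qz, frame$positions, fmat,
                            match(keys, ukeys))
  .new_pattern(qm$prefactor * fluence * amp2, qm, fluence = fluence)
}

#' Sum a series of diffraction patterns
#'
#' Pixelwise sum; all patterns must share one geometry.  Applied to the
#' instantaneous series of an explosion this yields the time-integrated
#' pattern a detector would record over the whole pulse.
#'
#' @param series Non-empty list of `diffraction_pattern`s.
#' @return A `diffraction_pattern` with mode `"integrated"`.
#' @export
integrate_time <- function(series) {
  if (length(series) == 0L) stop("empty pattern series", call. = FALSE)
  .check_shared_geometry(series)
  total <- Reduce(`+`, lapply(series, `[[`, "intensity"))
  out <- .new_pattern(total, series[[1]]$qmap, mode = "integrated",
                      fluence = sum(vapply(series, `[[`, numeric(1),
                                           "fluence")))
  out$frame_time <- series[[length(series)]]$frame_time
  out
}

.check_shared_geometry <- function(series) {
  g0 <- series[[1]]$qmap$geom
  for (p in series)
    if (!identical(p$qmap$geom, g0))
      stop("patterns do not share one detector geometry", call. = FALSE)
  invisible(TRUE)
}

#' Partially integrate a pattern series in time
#'
#' Sums the instantaneous patterns with frame time at or before `t_cut`;
#' a cut before the first frame yields a valid all-zero pattern.
#'
#' @param series List of `diffraction_pattern`s with frame times.
#' @param t_cut Integration cutoff in fs.
#' @return A `diffraction_pattern`.
#' @export
partial_integrate <- function(series, t_cut) {
  if (length(series) == 0L) stop("empty pattern series", call. = FALSE)
  keep <- vapply(series, function(p) !is.na(p$frame_time) &&
                   p$frame_time <= t_cut, logical(1))
  if (!any(keep)) {
    qm <- series[[1]]$qmap
    out <- .new_pattern(0 * series[[1]]$intensity, qm, mode = "integrated",
                        fluence = 0)
    out$frame_time <- t_cut
    return(out)
  }
  integrate_time(series[keep])
}

#' Instantaneous pattern series along a damage trajectory
#'
#' Evaluates fluence-weighted instantaneous patterns along an explosion.  The
#' damage `mode` isolates the two damage processes: `"full"` uses each frame's
#' positions and charge states, `"ionization_only"` freezes the atoms at the
#' first frame while applying the ionization data, and `"displacement_only"`
#' lets atoms move but keeps ground-state form factors.
#'
#' To keep the cost of ensemble runs proportionate, consecutive 0.5 fs frames
#' are grouped into at most `max_nodes` quadrature bins; each bin's pattern is
#' evaluated at its middle frame and weighted with the bin's exact integrated
#' fluence, so the summed fluence is preserved.
#'
#' @param traj A `damage_trajectory`.
#' @param geom A `detector_geometry` or `qmap`.
#' @param profile The `pulse_profile` that drove the explosion.
#' @param mode One of `"full"`, `"ionization_only"`, `"displacement_only"`.
#' @param max_nodes Maximum number of evaluated frames (default 32).
#' @param cache Optional form-factor cache environment.
#' @return List of `diffraction_pattern`s (one per quadrature bin, with
#'   `frame_time` set), suitable for [integrate_time()] /
#'   [partial_integrate()].
#' @export
trajectory_patterns <- function(traj, geom, profile,
                                mode = c("full", "ionization_only",
                                         "displacement_only"),
                                max_nodes = 32L, cache = NULL) {
  mode <- match.arg(mode)
  qm <- .as_qmap(geom)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ft <- traj$frame_times
  nf <- length(ft)
  photons <- .frame_photons(profile, ft)
  area <- focal_area(profile)
  ng <- min(max_nodes, nf)
  grp <- as.integer(cut(seq_len(nf), ng))
  gs <- ground_state_electrons(traj$elements)
  lapply(seq_len(ng), function(g) {
    idx <- which(grp == g)
    rep_f <- idx[ceiling(length(idx) / 2)]
    pos_f <- if (mode == "ionization_only") 1L else rep_f
    frame <- atomic_structure(
      traj$elements, traj$positions[, , pos_f],
      core_electrons = if (mode == "displacement_only") gs$core
                       else traj$core_electrons[, rep_f],
      valence_electrons = if (mode == "displacement_only") gs$valence
                          else traj$valence_electrons[, rep_f])
    pat <- pattern_instantaneous(frame, qm, sum(photons[idx]) / area, cache)
    pat$frame_time <- ft[rep_f]
    pat$mode <- mode
    pat
  })
}

#' First-frame (undamaged) pattern of a trajectory
#'
#' Unit-fluence instantaneous pattern of the starting structure; the
#' ensemble average of these is the undamaged reference against which
#' time-integrated patterns are correlated.  Pearson correlations are
#' invariant to the fluence scale, so unit fluence is used.
#'
#' @param traj A `damage_trajectory`.
#' @param geom A `detector_geometry` or `qmap`.
#' @param cache Optional form-factor cache.
#' @return A `diffraction_pattern`.
#' @export
first_frame_pattern <- function(traj, geom, cache = NULL) {
  qm <- .as_qmap(geom)
  gs <- ground_state_electrons(traj$elements)
  frame <- atomic_structure(traj$elements, traj$positions[, , 1],
                            core_electrons = gs$core,
                            valence_electrons = gs$valence)
  pat <- pattern_instantaneous(frame, qm, 1, cache)
  pat$frame_time <- traj$frame_times[1]
  pat$mode <- "first_frame"
  pat
}
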