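# Stochastic photoionization and Auger-decay model.
#
# Two electron reservoirs per atom: core (K shell, <= 2 electrons) and
# valence.  Photoionization removes an electron from either reservoir with
# probabilities set by tabulated shell cross sections scaled by the fraction
# of that shell still occupied (photoionized atoms become increasingly
# transparent).  Each core hole schedules an Auger decay after an
# exponentially distributed delay: the hole is refilled from the valence pool
# and a second valence electron is ejected, a net +1 in charge.  Secondary
# electron-impact ionization is deliberately excluded (worst-case explosion).

.xsec_env <- new.env(parent = emptyenv())

.xsec_table <- function() {
  if (is.null(.xsec_env$tab)) {
    .xsec_env$tab <- read.csv(.extdata("photoabsorption.csv"),
                              comment.char = "#")
    .xsec_env$auger <- read.csv(.extdata("auger_lifetimes.csv"),
                                comment.char = "#")
  }
  .xsec_env$tab
}

#' Photoionization cross sections per shell
#'
#' Looks up the tabulated total photoabsorption cross section (compiled from
#' the Cromer-Liberman anomalous-dispersion tabulation; see
#' `inst/extdata/photoabsorption.csv` for provenance) with log-log
#' interpolation between tabulated energies, and partitions it into K-shell
#' (core) and valence components.  Hydrogen has no core shell, so its full
#' cross section counts as valence.
#'
#' @param element Element symbol (H, C, N, O or S).
#' @param photon_energy Photon energy in keV; must lie within the tabulated
#'   range (6-10 keV).
#' @return Named numeric vector `c(core =, valence =)` in nm^2.
#' @examples
#' photo_cross_sections("C", 8)
#' @export
photo_cross_sections <- function(element, photon_energy) {
  .element_check(element)
  stopifnot(length(element) == 1L, length(photon_energy) == 1L)
  tab <- .xsec_table()
  rows <- tab[tab$element == element, ]
  if (photon_energy < min(rows$energy_kev) ||
      photon_energy > max(rows$energy_kev))
    stop(sprintf("photon energy %g keV outside tabulated range [%g, %g] keV",
                 photon_energy, min(rows$energy_kev), max(rows$energy_kev)),
         call. = FALSE)
  lsig <- approx(log(rows$energy_kev), log(rows$sigma_total_nm2),
                 xout = log(photon_energy))$y
  total <- exp(lsig)
  frac <- rows$core_fraction[1]
  c(core = total * frac, valence = total * (1 - frac))
}

#' Auger (core-hole) lifetime of an element
#' @param element Element symbol.
#' @return 1/e lifetime in fs (`NA` for hydrogen, which has no Auger channel).
#' @export
auger_lifetime <- function(element) {
  .element_check(element)
  .xsec_table()
  tab <- .xsec_env$auger
  tab$lifetime_fs[match(element, tab$element)]
}

#' Sample a stochastic ionization trajectory
#'
#' Runs the per-atom photoionization + Auger model over evenly spaced frames.
#' In each 0.5 fs step every atom draws Poisson-distributed core and valence
#' photoionization events with rate `sigma_shell * fluence`, where the shell
#' cross section is rescaled by the fraction of that shell still occupied and
#' the fluence is the step's photon count divided by the focal-spot area.
#' Core holes schedule Auger decays after exponential delays with
#' element-specific lifetimes; an Auger decay needs at least two remaining
#' valence electrons (it refills the hole and ejects one).
#'
#' @param structure An `atomic_structure` (its electron counts are the initial
#'   state).
#' @param profile A `pulse_profile`.
#' @param frame_times Evenly spaced frame times in fs (0.5 fs spacing by
#'   default conventions); defaults to [pulse_frame_times()].
#' @param seed Integer seed; trajectories are reproducible.
#' @return An `ionization_trajectory`: list with `frame_times`,
#'   `core_electrons` and `valence_electrons` (M x F integer matrices),
#'   `charges` (M x F), `elements`, and `event_log`
#'   (data frame time/atom/kind with kind in photo_core, photo_valence,
#'   auger).
#' @export
sample_ionization <- function(structure, profile,
                              frame_times = pulse_frame_times(profile),
                              seed = 1L) {
  m <- atom_count(structure)
  nf <- length(frame_times)
  if (nf > 1L) {
    dts <- diff(frame_times)
    if (max(abs(dts - dts[1])) > 1e-9)
      stop("frame_times must be evenly spaced", call. = FALSE)
  }
  el <- structure$elements
  gs <- ground_state_electrons(el)
  xs <- vapply(.supported_elements, photo_cross_sections,
               numeric(2), photon_energy = profile$photon_energy)
  sig_core0 <- xs["core", el]
  sig_val0 <- xs["valence", el]
  tau <- setNames(auger_lifetime(.supported_elements), .supported_elements)[el]
  photons <- .frame_photons(profile, frame_times)
  area <- focal_area(profile)

  .with_seed(seed, {
    core <- structure$core_electrons
    val <- structure$valence_electrons
    core_m <- matrix(0L, m, nf)
    val_m <- matrix(0L, m, nf)
    pend_atom <- integer(0)     # scheduled Auger decays
    pend_time <- numeric(0)
    log_t <- vector("list", nf)
    for (f in seq_len(nf)) {
      t_f <- frame_times[f]
      flu <- photons[f] / area
      ev_atom <- integer(0); ev_kind <- character(0)
      if (flu > 0) {
        nc <- rpois(m, sig_core0 * (core / pmax(gs$core, 1L)) * flu)
        nc <- pmin(nc, core)
        nv <- rpois(m, sig_val0 * (val / pmax(gs$valence, 1L)) * flu)
        nv <- pmin(nv, val)
        core <- core - nc
        val <- val - nv
        hit_c <- which(nc > 0L)
        if (length(hit_c)) {
          reps <- rep(hit_c, nc[hit_c])
          ev_atom <- c(ev_atom, reps)
          ev_kind <- c(ev_kind, rep("photo_core", length(reps)))
          delays <- rexp(length(reps), rate = 1 / tau[reps])
          pend_atom <- c(pend_atom, reps)
          pend_time <- c(pend_time, t_f + delays)
        }
        hit_v <- which(nv > 0L)
        if (length(hit_v)) {
          reps <- rep(hit_v, nv[hit_v])
          ev_atom <- c(ev_atom, reps)
          ev_kind <- c(ev_kind, rep("photo_valence", length(reps)))
        }
      }
      due <- which(pend_time <= t_f)
      if (length(due)) {
        for (idx in due) {
          a <- pend_atom[idx]
          if (core[a] < gs$core[a] && val[a] >= 2L) {
            core[a] <- core[a] + 1L
            val[a] <- val[a] - 2L
            ev_atom <- c(ev_atom, a)
            ev_kind <- c(ev_kind, "auger")
          }
        }
        pend_atom <- pend_atom[-due]
        pend_time <- pend_time[-due]
      }
      if (length(ev_atom))
        log_t[[f]] <- data.frame(time = t_f, atom = ev_atom, kind = ev_kind)
      core_m[, f] <- core
      val_m[, f] <- val
    }
    z <- .element_z(el)
    structure(list(frame_times = frame_times,
                   core_electrons = core_m,
                   valence_electrons = val_m,
                   charges = z - core_m - val_m,
                   elements = el,
                   event_log = do.call(rbind, log_t[!vapply(log_t, is.null,
                                                            logical(1))])),
              class = "ionization_trajectory")
  })
}

#' @export
print.ionization_trajectory <- function(x, ...) {
  nf <- length(x$frame_times)
  cat(sprintf(
    "ionization_trajectory: %d atoms, %d frames [%g, %g] fs, mean final charge %.3f\n",
    nrow(x$charges), nf, x$frame_times[1], x$frame_times[nf],
    mean(x$charges[, nf])))
  invisible(x)
}

#' Analytic expected ionization per atom
#'
#' Pre-saturation expectation of the number of charge-raising events per atom:
#' `sigma_total * Np / A` photoionizations, plus the core share doubled by the
#' probability that the Auger decay completes before the end of the
#' observation window (computed by integrating the pulse profile against the
#' exponential decay).  Depletion/saturation is ignored, so this is an upper
#' bound oracle used in tests.
#'
#' @param structure An `atomic_structure`.
#' @param profile A `pulse_profile`.
#' @param t_end End of the observation window in fs (default: end of
#'   [pulse_frame_times()]).
#' @return Numeric vector of expected events per atom.
#' @export
expected_ionization <- function(structure, profile,
                                t_end = max(pulse_frame_times(profile))) {
  el <- structure$elements
  xs <- vapply(.supported_elements, photo_cross_sections,
               numeric(2), photon_energy = profile$photon_energy)
  tau <- setNames(auger_lifetime(.supported_elements), .supported_elements)
  area <- focal_area(profile)
  flu <- profile$photon_count / area
  # P(Auger completes | core event), averaged over photon arrival times
  p_complete <- vapply(.supported_elements, function(e) {
    if (is.na(tau[e])) return(0)
    f <- function(t) gaussian_fluence(profile, t) / profile$photon_count *
      (1 - exp(-pmax(t_end - t, 0) / tau[e]))
    integrate(f, profile$center_time - 6 * profile$fwhm, t_end)$value
  }, numeric(1))
  unname((xs["core", el] * (1 + p_complete[el]) + xs["valence", el]) * flu)
}
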