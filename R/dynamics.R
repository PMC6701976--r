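# Coulomb-explosion surrogate dynamics.
#
# The analysis downstream consumes displacement statistics only, so the model
# keeps the minimum physics that drives them: Coulomb repulsion between the
# accumulating charges, breakable harmonic bonds that hold the intact regions
# together, and a steep short-range repulsion preventing overlap.  Atoms start
# at rest (structural variation is carried by the heterogeneous ensemble) and
# there is no thermostat, solvent, screening or periodic boundary.

.default_force_params <- function() {
  list(k_coulomb = .const$coulomb_k,  # eV nm
       r_soft = 0.05,                 # nm, Coulomb clamp radius
       k_bond = 30,                   # eV nm^-2
       break_factor = 1.5,            # bond severs past 1.5 r0
       rep_A = 5.65e-15,              # eV nm^12  (4 eps sigma^12,
       rep_cutoff = 0.22)             #  eps = 5 meV, sigma = 0.09 nm)
}

#' Build a bond list from structure geometry
#'
#' Bonds are inferred from interatomic distances rather than chemical
#' topology: heavy-atom pairs closer than `heavy_cutoff` and heavy-hydrogen
#' pairs closer than `h_cutoff` are restrained at their initial separation.
#' Hydrogen-hydrogen pairs are never bonded.
#'
#' @param structure An `atomic_structure`.
#' @param heavy_cutoff,h_cutoff Distance cutoffs in nm.
#' @return A list with `pairs` (B x 2 integer matrix of atom indices) and
#'   `r0` (rest lengths in nm).
#' @export
build_bonds <- function(structure, heavy_cutoff = 0.18, h_cutoff = 0.13) {
  pos <- structure$positions
  is_h <- structure$elements == "H"
  d <- as.matrix(dist(pos))
  cut <- matrix(heavy_cutoff, nrow(pos), nrow(pos))
  cut[is_h, ] <- h_cutoff
  cut[, is_h] <- h_cutoff
  cut[is_h, is_h] <- 0  # no H-H bonds
  sel <- which(upper.tri(d) & d < cut & d > 0, arr.ind = TRUE)
  list(pairs = unname(sel), r0 = d[sel])
}

#' Forces on every atom
#'
#' Sum of (a) pairwise Coulomb repulsion `k q_i q_j / r^2` with
#' `k = 1.4400 eV nm`, the separation clamped below 0.05 nm; (b) harmonic bond
#' restraints (30 eV/nm^2 about the initial bond length) that sever
#' permanently beyond 1.5 r0; and (c) a short-range `r^-12` repulsion between
#' non-bonded pairs.
#'
#' @param positions M x 3 matrix in nm.
#' @param charges Integer per-atom charges.
#' @param bonds Bond list from [build_bonds()] (or `NULL` for none).
#' @param params Force-field constants; see `xdn:::.default_force_params`.
#' @return List with `forces` (M x 3, eV/nm) and `energy` (named potential
#'   terms in eV).
#' @export
compute_forces <- function(positions, charges, bonds = NULL,
                           params = .default_force_params()) {
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("positions contain non-finite values",
                                       call. = FALSE)
  if (is.null(bonds)) bonds <- list(pairs = matrix(0L, 0, 2), r0 = numeric(0))
  .compute_forces_cpp(positions, as.numeric(charges),
                      as.matrix(bonds$pairs), as.numeric(bonds$r0), params)
}

#' Propagate a Coulomb explosion
#'
#' Velocity-Verlet integration (default step 0.05 fs) of the structure under
#' the forces of [compute_forces()], with per-atom charges taken from the
#' ionization trajectory and held constant between its 0.5 fs frames.
#' Atoms start at rest; positions are recorded at every frame boundary.
#'
#' @param structure An `atomic_structure` giving the initial positions.
#' @param ion_traj An `ionization_trajectory` covering the requested window.
#' @param t_end Final time in fs (default: last ionization frame).
#' @param dt Integrator substep in fs (default 0.05).
#' @param bonds Bond list; defaults to [build_bonds()] on the structure.
#' @param params Force-field constants.
#' @return A `damage_trajectory`: `frame_times` (fs), `positions`
#'   (M x 3 x F array, nm), `charges` (M x F), `energy` (F x 4 matrix:
#'   kinetic, coulomb, bond, repulsion, eV), `elements`, `masses`.
#' @export
run_explosion <- function(structure, ion_traj, t_end = NULL, dt = 0.05,
                          bonds = build_bonds(structure),
                          params = .default_force_params()) {
  ft <- ion_traj$frame_times
  if (is.null(t_end)) t_end <- ft[length(ft)]
  keep <- which(ft <= t_end + 1e-9)
  if (length(keep) < 2L)
    stop("ionization trajectory does not cover the requested window",
         call. = FALSE)
  ft <- ft[keep]
  charges <- ion_traj$charges[, keep, drop = FALSE]
  if (!all(is.finite(structure$positions)))
    stop("positions contain non-finite values", call. = FALSE)
  mass <- .element_mass(structure$elements) * .const$mass_ev
  res <- .explode_cpp(structure$positions, mass,
                      matrix(as.integer(charges), nrow = nrow(charges)),
                      ft, dt, as.matrix(bonds$pairs),
                      as.numeric(bonds$r0), params)
  structure(list(frame_times = ft, positions = res$positions,
                 charges = charges, energy = res$energy,
                 elements = structure$elements,
                 masses = .element_mass(structure$elements),
                 core_electrons = ion_traj$core_electrons[, keep, drop = FALSE],
                 valence_electrons = ion_traj$valence_electrons[, keep,
                                                                drop = FALSE],
                 final_velocities = res$final_velocities,
                 integrator_dt = dt),
            class = "damage_trajectory")
}

#' @export
print.damage_trajectory <- function(x, ...) {
  nf <- length(x$frame_times)
  rg0 <- radius_of_gyration(x$positions[, , 1], x$masses)
  rg1 <- radius_of_gyration(x$positions[, , nf], x$masses)
  cat(sprintf(
    "damage_trajectory: %d atoms, %d frames [%g, %g] fs, Rg %.3f -> %.3f nm\n",
    dim(x$positions)[1], nf, x$frame_times[1], x$frame_times[nf], rg0, rg1))
  invisible(x)
}

#' Mass-weighted radius of gyration
#'
#' @param positions M x 3 matrix in nm.
#' @param masses Per-atom masses (any consistent unit); unit masses by
#'   default.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(positions, masses = NULL) {
  positions <- as.matrix(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  w <- masses / sum(masses)
  com <- colSums(positions * w)
  sqrt(sum(w * rowSums(sweep(positions, 2L, com)^2)))
}

#' Frozen (no-motion) damage trajectory
#'
#' Builds a `damage_trajectory` whose atoms never move while carrying the
#' given ionization history — the control used to isolate ionization effects
#' (and, with an un-ionized history, the no-damage limit) without running the
#' integrator.
#'
#' @param structure An `atomic_structure` (fixed positions).
#' @param ion_traj An `ionization_trajectory`.
#' @return A `damage_trajectory` with identical positions at every frame.
#' @export
frozen_trajectory <- function(structure, ion_traj) {
  nf <- length(ion_traj$frame_times)
  m <- atom_count(structure)
  structure(list(frame_times = ion_traj$frame_times,
                 positions = array(structure$positions, c(m, 3L, nf)),
                 charges = ion_traj$charges,
                 energy = NULL,
                 elements = structure$elements,
                 masses = .element_mass(structure$elements),
                 core_electrons = ion_traj$core_electrons,
                 valence_electrons = ion_traj$valence_electrons,
                 final_velocities = matrix(0, m, 3L),
                 integrator_dt = NA_real_),
            class = "damage_trajectory")
}

# atomic_structure snapshot of trajectory frame f (positions + electron state)
.trajectory_frame <- function(traj, f) {
  atomic_structure(traj$elements, traj$positions[, , f],
                   core_electrons = traj$core_electrons[, f],
                   valence_electrons = traj$valence_electrons[, f])
}
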