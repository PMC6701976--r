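# Shared fixtures and independent oracles.

# small rigid test structures -------------------------------------------------

toy_structure <- function(elements = c("C", "N", "O"),
                          spacing = 0.15) {
  m <- length(elements)
  pos <- cbind((seq_len(m) - 1) * spacing, 0, 0)
  atomic_structure(elements, pos)
}

# compact bonded mini-globule (deterministic, n heavy atoms + hydrogens)
mini_globule <- function(n_heavy = 40, n_h = 20, seed = 7) {
  s <- generate_lysozyme_like(seed)
  heavy <- which(s$elements != "H")[seq_len(n_heavy)]
  hyd <- which(s$elements == "H")[seq_len(n_h)]
  sel <- c(heavy, hyd)
  atomic_structure(s$elements[sel], s$positions[sel, , drop = FALSE])
}

# hand-built ionization history with constant charges (charge on every atom)
constant_ionization <- function(structure, charge, frame_times) {
  m <- atom_count(structure)
  nf <- length(frame_times)
  gs <- ground_state_electrons(structure$elements)
  val <- pmax(gs$valence - charge, 0L)
  core <- gs$core - pmax(charge - gs$valence, 0L)
  structure(list(frame_times = frame_times,
                 core_electrons = matrix(core, m, nf),
                 valence_electrons = matrix(val, m, nf),
                 charges = matrix(gs$z - core - val, m, nf),
                 elements = structure$elements,
                 event_log = NULL),
            class = "ionization_trajectory")
}

# independent diffraction oracle ----------------------------------------------

# Direct pairwise evaluation of the diffraction sum:
# I = pref * F * [ sum_i f_i^2 + 2 sum_i sum_{j<i} f_i f_j cos(2 pi q.(Ri-Rj)) ]
pairwise_pattern_oracle <- function(frame, qmap, fluence = 1) {
  m <- atom_count(frame)
  gs <- ground_state_electrons(frame$elements)
  f <- sapply(seq_len(m), function(i)
    ionic_form_factor(frame$elements[i],
                      gs$core[i] - frame$core_electrons[i],
                      frame$valence_electrons[i], qmap$qmag))
  np <- length(qmap$qmag)
  acc <- rowSums(f^2)
  if (m > 1) {
    for (i in 2:m) for (j in 1:(i - 1)) {
      dR <- frame$positions[i, ] - frame$positions[j, ]
      phase <- 2 * pi * (qmap$qx * dR[1] + qmap$qy * dR[2] + qmap$qz * dR[3])
      acc <- acc + 2 * f[, i] * f[, j] * cos(phase)
    }
  }
  matrix(qmap$prefactor * fluence * acc, qmap$geom$n_pixels)
}

# standard neutral-atom form factors (International Tables 4-Gaussian fits;
# argument s = sin(theta)/lambda in 1/Angstrom)
it92_coefs <- list(
  H = list(a = c(0.493002, 0.322912, 0.140191, 0.04081),
           b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C = list(a = c(2.31, 1.02, 1.5886, 0.865),
           b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
           b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
  O = list(a = c(3.0485, 2.2868, 1.5463, 0.867),
           b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  S = list(a = c(6.9053, 5.2034, 1.4379, 1.5863),
           b = c(1.4679, 22.2151, 0.2536, 56.172), c = 0.8669))

it92_ff <- function(element, q_nm) {
  s2 <- (q_nm / 20)^2  # q nm^-1 -> (sin th / lambda)^2 in 1/A^2
  cf <- it92_coefs[[element]]
  vapply(s2, function(x) sum(cf$a * exp(-cf$b * x)) + cf$c, numeric(1))
}

# small detector used throughout unit tests (full q range, few pixels)
test_geometry <- function(n = 32L) detector_geometry(n, 256 / n * 33.8, 3, 8)
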