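# Atomic structures, PDB I/O, the synthetic lysozyme-like globule and the
# calibrated heterogeneity generator.

#' Construct an atomic structure
#'
#' An `atomic_structure` holds the chemical identity, position and electron
#' bookkeeping of every atom in the sample.  Positions are in nanometres.
#' Electrons are split into at most two core (K-shell) electrons and a valence
#' pool; hydrogen's single electron is valence by convention.
#'
#' @param elements Character vector of element symbols (H, C, N, O, S).
#' @param positions Numeric matrix (M x 3) of coordinates in nm.
#' @param core_electrons,valence_electrons Optional integer vectors of per-atom
#'   electron counts; default to the neutral ground state.
#' @return An object of class `atomic_structure` with fields `elements`,
#'   `positions`, `core_electrons`, `valence_electrons`.
#' @examples
#' s <- atomic_structure(c("C", "O"), rbind(c(0, 0, 0), c(0.12, 0, 0)))
#' atom_count(s)
#' @export
atomic_structure <- function(elements, positions,
                             core_electrons = NULL, valence_electrons = NULL) {
  .element_check(elements)
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L)
    stop("positions must be an M x 3 numeric matrix (nm)", call. = FALSE)
  m <- length(elements)
  if (nrow(positions) != m)
    stop("elements and positions disagree on atom count", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("positions must all be finite", call. = FALSE)
  gs <- ground_state_electrons(elements)
  if (is.null(core_electrons)) core_electrons <- gs$core
  if (is.null(valence_electrons)) valence_electrons <- gs$valence
  core_electrons <- as.integer(core_electrons)
  valence_electrons <- as.integer(valence_electrons)
  if (length(core_electrons) != m || length(valence_electrons) != m)
    stop("electron counts must have one entry per atom", call. = FALSE)
  if (any(core_electrons < 0L) || any(core_electrons > 2L))
    stop("core_electrons must lie in [0, 2]", call. = FALSE)
  if (any(valence_electrons < 0L))
    stop("valence_electrons must be non-negative", call. = FALSE)
  if (any(core_electrons + valence_electrons > gs$z))
    stop("electron counts exceed the atomic number", call. = FALSE)
  dimnames(positions) <- NULL
  structure(list(elements = elements, positions = positions,
                 core_electrons = core_electrons,
                 valence_electrons = valence_electrons),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  comp <- table(x$elements)
  cat("atomic_structure:", atom_count(x), "atoms (",
      paste0(names(comp), comp, collapse = " "), ")\n")
  cat("  total charge:", sum(structure_charges(x)),
      " extent:", sprintf("%.2f nm\n", max(dist(x$positions))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure An `atomic_structure`.
#' @return Integer atom count M.
#' @export
atom_count <- function(structure) length(structure$elements)

#' Per-atom charge states
#'
#' Charge is the ground-state electron count minus the electrons still bound,
#' and is never negative.
#'
#' @param structure An `atomic_structure`.
#' @return Integer vector of per-atom charges.
#' @export
structure_charges <- function(structure) {
  z <- .element_z(structure$elements)
  as.integer(z - structure$core_electrons - structure$valence_electrons)
}

# run `expr` under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# ---------------------------------------------------------------------------
# PDB I/O

.pdb_element <- function(rec, lineno) {
  el <- toupper(trimws(substr(rec, 77, 78)))
  if (!nzchar(el)) {
    # fallback: first alphabetic character of the atom-name field
    nm <- gsub("[^A-Za-z]", "", substr(rec, 13, 16))
    el <- toupper(substr(nm, 1, 1))
  }
  if (!el %in% .supported_elements)
    stop(sprintf("line %d: unsupported element '%s' (only H, C, N, O, S)",
                 lineno, el), call. = FALSE)
  el
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM and HETATM records (fixed-column format, coordinates in
#' Angstrom), resolves the element from the element column with a fallback to
#' the atom-name field, converts to nm and initialises every atom to its
#' neutral ground state.  Occupancy and B-factor are ignored.
#'
#' @param path Path to a PDB-format text file.
#' @return An `atomic_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (length(sel) == 0L)
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  n <- length(sel)
  pos <- matrix(NA_real_, n, 3L)
  el <- character(n)
  for (k in seq_len(n)) {
    rec <- lines[sel[k]]
    xyz <- suppressWarnings(as.numeric(c(substr(rec, 31, 38),
                                         substr(rec, 39, 46),
                                         substr(rec, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("line %d: unparseable coordinates in '%s'",
                   sel[k], trimws(rec)), call. = FALSE)
    pos[k, ] <- xyz
    el[k] <- .pdb_element(rec, sel[k])
  }
  atomic_structure(el, pos / 10)  # Angstrom -> nm
}

#' Write an atomic structure to a PDB file
#'
#' Emits one ATOM record per atom (coordinates back-converted to Angstrom,
#' occupancy 1.00, B-factor 0.00).
#'
#' @param structure An `atomic_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  pos <- structure$positions * 10  # nm -> Angstrom
  el <- structure$elements
  recs <- sprintf(
    "ATOM  %5d %-4s%-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_along(el) %% 100000L, sprintf(" %s", el), "UNK", 1L,
    pos[, 1], pos[, 2], pos[, 3], 1.0, 0.0, el)
  writeLines(c(recs, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Synthetic sample

# sequential min-distance placement in a ball using a coarse cell grid
.place_ball <- function(n, radius, min_dist, max_tries = 200L) {
  pos <- matrix(0, n, 3L)
  cell <- min_dist
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(ix) paste(ix, collapse = ",")
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      ix <- floor(p / cell)
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        neigh <- grid[[key(ix + c(dx, dy, dz))]]
        if (!is.null(neigh)) {
          d2 <- colSums((t(pos[neigh, , drop = FALSE]) - p)^2)
          if (any(d2 < min_dist^2)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        pos[k, ] <- p
        kk <- key(ix)
        grid[[kk]] <- c(grid[[kk]], k)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("failed to place atom ", k, "; density too high", call. = FALSE)
  }
  pos
}

#' Generate a lysozyme-like synthetic structure
#'
#' Builds a compact globule with the exact hen egg-white lysozyme composition
#' C613 H959 N193 O185 S10 (1960 atoms).  Heavy atoms (C, N, O, S) are placed
#' at protein-like density (about 60 heavy atoms per nm^3) with a minimum
#' separation of 0.11 nm inside a sphere; each hydrogen is attached 0.105 nm
#' from a randomly chosen heavy parent.  The construction is deterministic for
#' a fixed seed and the globule diameter is well below 10 nm.
#'
#' @param seed Integer seed controlling the geometry.
#' @return An `atomic_structure` of 1960 atoms in the neutral ground state.
#' @examples
#' s <- generate_lysozyme_like(1)
#' table(s$elements)
#' @export
generate_lysozyme_like <- function(seed = 1L) {
  comp <- c(C = 613L, H = 959L, N = 193L, O = 185L, S = 10L)
  .with_seed(seed, {
    heavy <- c(rep("C", comp["C"]), rep("N", comp["N"]),
               rep("O", comp["O"]), rep("S", comp["S"]))
    heavy <- sample(heavy)
    n_heavy <- length(heavy)
    radius <- (3 * n_heavy / (4 * pi * 60))^(1 / 3)  # 60 heavy atoms / nm^3
    hpos <- .place_ball(n_heavy, radius, 0.11)
    # hydrogens: bonded 0.105 nm from C/N/O parents (capped coordination),
    # kept >= 0.11 nm from other heavy atoms and >= 0.15 nm from other
    # hydrogens (geminal H...H contact scale), so non-bonded contacts start
    # outside the short-range repulsion
    w <- c(C = 1.0, N = 0.6, O = 0.3, S = 0.0)[heavy]
    cap <- c(C = 3L, N = 3L, O = 2L, S = 0L)[heavy]
    used <- integer(n_heavy)
    hyd <- matrix(0, comp["H"], 3L)
    n_hyd <- 0L
    for (k in seq_len(comp["H"])) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        parent <- sample.int(n_heavy, 1L, prob = w * (used < cap))
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p <- hpos[parent, ] + 0.105 * u
        d2h <- colSums((t(hpos) - p)^2)
        d2h[parent] <- Inf
        hh_min <- if (try <= 200L) 0.15 else 0.13
        if (min(d2h) < 0.11^2) next
        if (n_hyd > 0L &&
            min(colSums((t(hyd[seq_len(n_hyd), , drop = FALSE]) - p)^2)) <
              hh_min^2) next
        ok <- TRUE
        break
      }
      if (!ok) stop("failed to place hydrogen ", k, call. = FALSE)
      used[parent] <- used[parent] + 1L
      n_hyd <- n_hyd + 1L
      hyd[n_hyd, ] <- p
    }
    atomic_structure(c(heavy, rep("H", comp["H"])), rbind(hpos, hyd))
  })
}

# ---------------------------------------------------------------------------
# Heterogeneity

#' Pairwise RMSD between two conformations
#'
#' Root-mean-square deviation over the selected atoms, computed in the shared
#' laboratory frame without rigid-body superposition (all simulations share
#' one orientation, so rigid components of the displacement are
#' diffraction-relevant and are kept).
#'
#' @param a,b `atomic_structure` objects with identical element sequences.
#' @param heavy_only If `TRUE` (default) only C, N, O and S atoms — the atoms
#'   that contribute significantly to scattering — enter the average.
#' @param superpose If `TRUE`, remove the optimal rigid translation first
#'   (rotation is never fitted); off by default.
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(a, b, heavy_only = TRUE, superpose = FALSE) {
  if (!identical(a$elements, b$elements))
    stop("structures have different element sequences", call. = FALSE)
  sel <- if (heavy_only) a$elements != "H" else rep(TRUE, atom_count(a))
  d <- a$positions[sel, , drop = FALSE] - b$positions[sel, , drop = FALSE]
  if (superpose) d <- sweep(d, 2L, colMeans(d))
  sqrt(mean(rowSums(d^2))) * 10  # nm -> Angstrom
}

#' Mean pairwise RMSD of an ensemble
#' @param ensemble A `structure_ensemble`.
#' @inheritParams pairwise_rmsd
#' @return Mean of all unordered pairwise RMSDs, in Angstrom.
#' @export
mean_pairwise_rmsd <- function(ensemble, heavy_only = TRUE) {
  n <- length(ensemble$members)
  if (n < 2L) return(0)
  prs <- combn(n, 2L)
  mean(apply(prs, 2L, function(ij)
    pairwise_rmsd(ensemble$members[[ij[1]]], ensemble$members[[ij[2]]],
                  heavy_only = heavy_only)))
}

# smooth correlated displacement field: a few random long-wavelength
# plane-wave modes per Cartesian component
.displacement_field <- function(positions, n_modes = 8L,
                                wavelength = c(1.0, 3.0)) {
  m <- nrow(positions)
  u <- matrix(0, m, 3L)
  for (mode in seq_len(n_modes)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    lam <- runif(1, wavelength[1], wavelength[2])
    phase <- runif(1, 0, 2 * pi)
    amp <- rnorm(3)
    s <- sin(2 * pi * (positions %*% dir) / lam + phase)
    u <- u + s %*% t(amp)
  }
  sweep(u, 2L, colMeans(u))  # no net rigid translation
}

#' Build a heterogeneous starting-structure ensemble
#'
#' Emulates conformational sample heterogeneity by adding smooth, spatially
#' correlated displacement fields (a sum of random long-wavelength plane-wave
#' modes, not independent per-atom jitter) to a reference structure.  All
#' members' fields are rescaled by one common factor so that the mean pairwise
#' heavy-atom RMSD (no superposition) matches `target_rmsd` exactly.
#'
#' @param structure Reference `atomic_structure`.
#' @param n Number of ensemble members (>= 1).
#' @param target_rmsd Target mean pairwise heavy-atom RMSD in Angstrom
#'   (default 0.95, the calibration used throughout the package).
#' @param seed Integer seed.
#' @return A `structure_ensemble`: list with `members` (list of
#'   `atomic_structure`) and `target_rmsd`.
#' @export
perturb_ensemble <- function(structure, n, target_rmsd = 0.95, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (target_rmsd < 0) stop("target_rmsd must be >= 0", call. = FALSE)
  members <- .with_seed(seed, {
    if (n == 1L || target_rmsd == 0) {
      replicate(n, structure, simplify = FALSE)
    } else {
      fields <- replicate(n, .displacement_field(structure$positions),
                          simplify = FALSE)
      heavy <- structure$elements != "H"
      prs <- combn(n, 2L)
      cur <- mean(apply(prs, 2L, function(ij) {
        d <- (fields[[ij[1]]] - fields[[ij[2]]])[heavy, , drop = FALSE]
        sqrt(mean(rowSums(d^2))) * 10
      }))
      scale <- target_rmsd / cur
      lapply(fields, function(u) {
        s <- structure
        s$positions <- s$positions + scale * u
        s
      })
    }
  })
  structure(list(members = members, target_rmsd = target_rmsd),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble:", length(x$members), "members,",
      "target mean pairwise RMSD", x$target_rmsd, "Angstrom\n")
  invisible(x)
}
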