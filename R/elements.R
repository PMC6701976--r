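# Per-element data for the supported species (H, C, N, O, S).
#
# The electron bookkeeping follows the two-shell convention of the ionization
# model: at most two "core" (K-shell) electrons per atom, everything else is
# "valence".  Hydrogen's single electron is treated as valence, so it has no
# core shell and no Auger channel.

.elements <- data.frame(
  symbol  = c("H", "C", "N", "O", "S"),
  z       = c(1L, 6L, 7L, 8L, 16L),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06),  # u, isotope-averaged
  core    = c(0L, 2L, 2L, 2L, 2L),
  valence = c(1L, 4L, 5L, 6L, 14L),
  stringsAsFactors = FALSE
)
rownames(.elements) <- .elements$symbol

.supported_elements <- .elements$symbol

.element_check <- function(elements) {
  bad <- setdiff(unique(elements), .supported_elements)
  if (length(bad) > 0L) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (only H, C, N, O, S are modelled)", call. = FALSE)
  }
  invisible(elements)
}

#' Ground-state electron bookkeeping for an element
#'
#' Returns the number of core (K-shell, at most two) and valence electrons an
#' atom of the given element carries in its neutral ground state.  Hydrogen's
#' single electron counts as valence.
#'
#' @param element Character vector of element symbols (H, C, N, O or S).
#' @return A data frame with columns `z`, `core` and `valence`, one row per
#'   input element.
#' @examples
#' ground_state_electrons(c("C", "H"))
#' @export
ground_state_electrons <- function(element) {
  .element_check(element)
  out <- .elements[element, c("z", "core", "valence")]
  rownames(out) <- NULL
  out
}

.element_z <- function(elements) .elements[elements, "z"]
.element_mass <- function(elements) .elements[elements, "mass"]

# Single-zeta Slater-orbital exponents used for the ionic form factors.
# 1s exponents are the Clementi-Raimondi optimal single-zeta values; the
# valence exponents were refined once against the standard IT92 neutral-atom
# form-factor tables over the detector q range (worst deviation 0.32%).
# Hydrogen uses the contracted bonded-atom exponent consistent with the
# Stewart-Davidson-Simpson treatment adopted by the standard tables.
.slater_shells <- list(
  H = data.frame(shell = "1s", n = 1L, zeta = 1.1601, cap = 1L),
  C = data.frame(shell = c("1s", "2s", "2p"), n = c(1L, 2L, 2L),
                 zeta = c(5.6727, 1.2775, 1.8252), cap = c(2L, 2L, 6L)),
  N = data.frame(shell = c("1s", "2s", "2p"), n = c(1L, 2L, 2L),
                 zeta = c(6.6651, 2.4123, 1.5319), cap = c(2L, 2L, 6L)),
  O = data.frame(shell = c("1s", "2s", "2p"), n = c(1L, 2L, 2L),
                 zeta = c(7.6579, 3.1079, 1.7922), cap = c(2L, 2L, 6L)),
  S = data.frame(shell = c("1s", "2s", "2p", "3s", "3p"),
                 n = c(1L, 2L, 2L, 3L, 3L),
                 zeta = c(15.5409, 7.1676, 4.9749, 2.5075, 1.5884),
                 cap = c(2L, 2L, 6L, 2L, 6L))
)

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "xdn")
  if (!nzchar(path)) stop("missing package data file: ", file, call. = FALSE)
  path
}
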