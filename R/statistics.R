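# Ensemble statistics: per-pixel moments, masked Pearson correlations,
# heterogeneity and shot-noise baselines, resolution-shell profiles, speckle
# contrast, signal-to-noise ratios and gating curves.

#' Per-pixel ensemble statistics
#'
#' Pixelwise mean and population variance (1/N convention) over an ensemble
#' of patterns, optionally with an undamaged reference mean attached.
#'
#' @param patterns Non-empty list of `diffraction_pattern`s sharing one
#'   geometry (typically time-integrated patterns, one per explosion).
#' @param mu0 Optional undamaged reference: a `diffraction_pattern`, or a
#'   list of first-frame patterns that will be averaged.
#' @return A `pattern_ensemble`: `mu` and `var` (n x n matrices), `mu0`
#'   (matrix or `NULL`), `n`, `qmap`.
#' @export
ensemble_stats <- function(patterns, mu0 = NULL) {
  if (length(patterns) == 0L) stop("empty pattern list", call. = FALSE)
  .check_shared_geometry(patterns)
  n <- length(patterns)
  mats <- lapply(patterns, `[[`, "intensity")
  mu <- Reduce(`+`, mats) / n
  v <- Reduce(`+`, lapply(mats, function(m) (m - mu)^2)) / n
  if (!is.null(mu0)) {
    if (inherits(mu0, "diffraction_pattern")) mu0 <- mu0$intensity
    else if (is.list(mu0))
      mu0 <- Reduce(`+`, lapply(mu0, `[[`, "intensity")) / length(mu0)
  }
  structure(list(mu = mu, var = v, mu0 = mu0, n = n,
                 qmap = patterns[[1]]$qmap),
            class = "pattern_ensemble")
}

#' @export
print.pattern_ensemble <- function(x, ...) {
  cat(sprintf("pattern_ensemble: %d patterns of %d x %d px (mu0 %s)\n",
              x$n, nrow(x$mu), ncol(x$mu),
              if (is.null(x$mu0)) "absent" else "attached"))
  invisible(x)
}

#' Masked pixelwise Pearson correlation
#'
#' Pearson correlation between two pixel maps over the pixels outside the
#' central-speckle mask (`|q| > q_cutoff`; the default 0.65 nm^-1 removes
#' everything coarser than ~15 A, which overlaps the unscattered beam).  The
#' two-sided p-value uses the t approximation with (#unmasked pixels - 2)
#' degrees of freedom.
#'
#' @param map_a,map_b Matrices (or `diffraction_pattern`s) on the qmap's grid.
#' @param qmap The `qmap` describing the grid.
#' @param q_cutoff Mask radius in nm^-1 (default 0.65).
#' @return A `correlation_report` list: `r`, `p_value`, `n_pixels`,
#'   `q_cutoff`.
#' @export
masked_pearson <- function(map_a, map_b, qmap, q_cutoff = 0.65) {
  if (inherits(map_a, "diffraction_pattern")) map_a <- map_a$intensity
  if (inherits(map_b, "diffraction_pattern")) map_b <- map_b$intensity
  mask <- qmap$qmag > q_cutoff
  a <- as.vector(map_a)[mask]
  b <- as.vector(map_b)[mask]
  if (length(a) < 3L) stop("fewer than 3 pixels outside the mask",
                           call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("degenerate input: zero variance outside the mask", call. = FALSE)
  r <- cor(a, b)
  df <- length(a) - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p_value = 2 * pt(-abs(tstat), df),
                 n_pixels = length(a), q_cutoff = q_cutoff),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("masked Pearson r = %.4f (p = %.3g, %d pixels, q > %g nm^-1)\n",
              x$r, x$p_value, x$n_pixels, x$q_cutoff))
  invisible(x)
}

#' Sample-heterogeneity correlation baseline
#'
#' Distribution of the masked Pearson correlation between noiseless
#' first-frame patterns of randomly drawn pairs of starting structures: the
#' level of pattern similarity that sample heterogeneity alone permits.
#'
#' @param ensemble A `structure_ensemble` (>= 2 members).
#' @param geom A `detector_geometry` or `qmap`.
#' @param iterations Number of random pairs (default 500).
#' @param seed Integer seed.
#' @param q_cutoff Mask radius in nm^-1.
#' @return List with `r` (per-iteration values), `mean`, `sd`.
#' @export
heterogeneity_baseline <- function(ensemble, geom, iterations = 500L,
                                   seed = 1L, q_cutoff = 0.65) {
  n <- length(ensemble$members)
  if (n < 2L) stop("need at least 2 structures", call. = FALSE)
  qm <- .as_qmap(geom)
  cache <- new.env(parent = emptyenv())
  pats <- lapply(ensemble$members, function(s)
    pattern_instantaneous(s, qm, 1, cache)$intensity)
  r <- .with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      ij <- sample.int(n, 2L)
      masked_pearson(pats[[ij[1]]], pats[[ij[2]]], qm, q_cutoff)$r
    }, numeric(1))
  })
  list(r = r, mean = mean(r), sd = sd(r))
}

#' Shot-noise correlation baseline
#'
#' Poisson-samples one noiseless full-intensity instantaneous pattern twice
#' per iteration and correlates the two noisy copies under the mask: the
#' correlation level attainable in the presence of photon shot noise alone.
#'
#' @param structure An `atomic_structure`.
#' @param geom A `detector_geometry` or `qmap`.
#' @param profile A `pulse_profile`; the pattern is computed at full pulse
#'   fluence `Np / focal area`.
#' @param iterations Number of iterations (default 500).
#' @param seed Integer seed.
#' @param q_cutoff Mask radius in nm^-1.
#' @return List with `r`, `mean`, `sd`.
#' @export
shot_noise_baseline <- function(structure, geom, profile, iterations = 500L,
                                seed = 1L, q_cutoff = 0.65) {
  qm <- .as_qmap(geom)
  flu <- profile$photon_count / focal_area(profile)
  lambda <- pattern_instantaneous(structure, qm, flu)$intensity
  mask <- qm$qmag > q_cutoff
  lam <- as.vector(lambda)[mask]
  if (all(lam == 0)) stop("degenerate input: all-zero pattern", call. = FALSE)
  r <- .with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      a <- rpois(length(lam), lam)
      b <- rpois(length(lam), lam)
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
  })
  r <- r[!is.na(r)]
  list(r = r, mean = mean(r), sd = sd(r))
}

# integer-pixel-radius shell index per pixel (1-based; shell s collects
# pixels with round(radius) == s - 1)
.shell_index <- function(qmap) as.integer(round(qmap$pixel_radius)) + 1L

#' Resolution-shell radial profiles
#'
#' Radially averages the ensemble maps over one-pixel-wide annuli centred on
#' the beam: shell mean intensity `mu(q)`, damage noise `sigma(q)` (sqrt of
#' the shell-averaged ensemble variance), shot noise `sqrt(mu(q))`, and the
#' speckle contrast `sigma_I(q)` — the standard deviation of the mean
#' pattern's pixel values within the shell, i.e. the imaging signal.
#'
#' @param ensemble A `pattern_ensemble`.
#' @return A `shell_statistics` data frame with one row per shell: `shell`,
#'   `q` (mean |q|, nm^-1), `resolution` (A), `n_pixels`, `mu`, `sigma`,
#'   `shot`, `sigma_I` (and `mu0` when a reference is attached).
#' @export
radial_profiles <- function(ensemble) {
  qm <- ensemble$qmap
  idx <- .shell_index(qm)
  npix <- tabulate(idx)
  shells <- which(npix > 0L)
  mu_q <- tapply(as.vector(ensemble$mu), idx, mean)
  var_q <- tapply(as.vector(ensemble$var), idx, mean)
  # population SD of the mean pattern within the shell (speckle contrast)
  m2 <- tapply(as.vector(ensemble$mu)^2, idx, mean)
  sig_i <- sqrt(pmax(m2 - mu_q^2, 0))
  q_q <- tapply(qm$qmag, idx, mean)
  out <- data.frame(shell = shells,
                    q = as.numeric(q_q),
                    resolution = 10 / as.numeric(q_q),
                    n_pixels = npix[shells],
                    mu = as.numeric(mu_q),
                    sigma = sqrt(pmax(as.numeric(var_q), 0)),
                    shot = sqrt(pmax(as.numeric(mu_q), 0)),
                    sigma_I = as.numeric(sig_i))
  if (!is.null(ensemble$mu0))
    out$mu0 <- as.numeric(tapply(as.vector(ensemble$mu0), idx, mean))
  class(out) <- c("shell_statistics", "data.frame")
  out
}

#' Per-shell Pearson correlation to the undamaged reference
#'
#' Correlates the mean time-integrated pattern with the mean first-frame
#' pattern across the pixels of each resolution shell, with shell-mean
#' subtraction.  Shells with fewer than 3 pixels or zero variance on either
#' side are flagged invalid rather than silently zeroed.
#'
#' @param ensemble A `pattern_ensemble` with `mu0` attached.
#' @return Data frame: `shell`, `q`, `r`, `p_value`, `valid`.
#' @export
shell_pearson <- function(ensemble) {
  if (is.null(ensemble$mu0))
    stop("ensemble has no undamaged reference mu0", call. = FALSE)
  qm <- ensemble$qmap
  idx <- .shell_index(qm)
  mu <- as.vector(ensemble$mu)
  mu0 <- as.vector(ensemble$mu0)
  shells <- sort(unique(idx))
  res <- lapply(shells, function(s) {
    sel <- idx == s
    a <- mu[sel]; b <- mu0[sel]
    if (length(a) < 3L || sd(a) == 0 || sd(b) == 0)
      return(data.frame(shell = s, q = mean(qm$qmag[sel]), r = NA_real_,
                        p_value = NA_real_, valid = FALSE))
    r <- cor(a, b)
    df <- length(a) - 2L
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(shell = s, q = mean(qm$qmag[sel]), r = r,
               p_value = 2 * pt(-abs(tstat), df), valid = TRUE)
  })
  do.call(rbind, res)
}

#' Shell signal-to-noise ratios
#'
#' Adds the three SNR columns to a shell table: `snr_shot =
#' sigma_I/sqrt(mu)`, `snr_damage = sigma_I/sigma` and `snr_total =
#' sigma_I/(sqrt(mu) + sigma)`.  Shells with a zero denominator get `NA`
#' (flagged undefined, never infinity), except that `snr_damage` and
#' `snr_total` reduce exactly to their shot-noise forms when the damage noise
#' is zero.
#'
#' @param shells A `shell_statistics` data frame from [radial_profiles()].
#' @return The input with columns `snr_shot`, `snr_damage`, `snr_total`
#'   added.
#' @export
snr_profiles <- function(shells) {
  safe_div <- function(a, b) ifelse(b > 0, a / b, ifelse(a == 0, 0, NA_real_))
  shells$snr_shot <- safe_div(shells$sigma_I, shells$shot)
  shells$snr_damage <- safe_div(shells$sigma_I, shells$sigma)
  shells$snr_total <- safe_div(shells$sigma_I, shells$shot + shells$sigma)
  shells
}

#' SNR accumulation (gating) curve
#'
#' Partially integrates every explosion's pattern series up to successive
#' time cuts, recomputes the ensemble shell statistics at each cut and
#' reports the total SNR at the shell nearest the requested resolution.  A
#' plateau before pulse end is the diffraction self-gating signature: damage
#' terminates useful signal accretion while photons are still arriving.
#'
#' @param series_list List (one per explosion) of pattern series from
#'   [trajectory_patterns()].
#' @param shell_resolution Resolution of interest in Angstrom (default 5).
#' @param t_cuts Time cuts in fs (default: every quadrature node time).
#' @return Data frame: `t_cut`, `snr_total`, `q`, `resolution`.
#' @export
gating_curve <- function(series_list, shell_resolution = 5,
                         t_cuts = NULL) {
  if (length(series_list) < 2L)
    stop("need at least 2 explosions", call. = FALSE)
  if (is.null(t_cuts))
    t_cuts <- vapply(series_list[[1]], `[[`, numeric(1), "frame_time")
  rows <- lapply(t_cuts, function(tc) {
    ints <- lapply(series_list, partial_integrate, t_cut = tc)
    sh <- snr_profiles(radial_profiles(ensemble_stats(ints)))
    sh <- sh[sh$n_pixels >= 3L & sh$q > 0, ]
    i <- which.min(abs(sh$resolution - shell_resolution))
    data.frame(t_cut = tc, snr_total = sh$snr_total[i], q = sh$q[i],
               resolution = sh$resolution[i])
  })
  do.call(rbind, rows)
}

#' Patterns needed to close an SNR gap by averaging
#'
#' Averaging N independent patterns suppresses both shot and damage noise by
#' sqrt(N), so closing a k-fold SNR gap costs a factor k^2 in patterns.
#'
#' @param snr_ratio The SNR factor to recover (k).
#' @return Number of patterns (k^2).
#' @examples
#' averaging_factor(4)  # 16 patterns recover a 4-fold SNR gap
#' @export
averaging_factor <- function(snr_ratio) snr_ratio^2
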