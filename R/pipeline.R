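# End-to-end orchestration: config validation, staged pipeline runs,
# artifact persistence and provenance.

.default_config <- function() {
  list(
    sample = list(source = "synthetic", pdb_path = NULL,
                  ensemble_size = 20L, heterogeneity_rmsd = 0.95),
    pulses = list(list(photon_count = 1e12, fwhm = 50,
                       photon_energy = 8, focus_diameter = 100)),
    detector = list(n_pixels = 256L, pixel_size = 33.8, distance = 3),
    dynamics = list(frame_dt = 0.5, integrator_dt = 0.05),
    analysis = list(mask_cutoff = 0.65, baseline_iterations = 500L,
                    max_nodes = 32L, mode = "full", gating = FALSE,
                    shell_resolution = 5),
    seed = 1L
  )
}

.check_known_keys <- function(given, known, where) {
  bad <- setdiff(names(given), known)
  if (length(bad)) {
    hint <- vapply(bad, function(b) {
      d <- adist(b, known)
      if (min(d) <= 2) sprintf(" (did you mean '%s'?)", known[which.min(d)])
      else ""
    }, character(1))
    stop("unknown config key", if (length(bad) > 1) "s", " in ", where, ": ",
         paste0("'", bad, "'", hint, collapse = ", "), call. = FALSE)
  }
}

.check_positive <- function(cfg, section, keys) {
  for (k in keys) {
    v <- cfg[[section]][[k]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0)))
      stop(sprintf("config key %s.%s must be a positive number", section, k),
           call. = FALSE)
  }
}

#' Validate and complete a pipeline configuration
#'
#' Merges a (possibly nested, possibly empty) configuration list over the
#' package defaults — the reference experiment: synthetic lysozyme-like
#' sample, 0.95 A heterogeneity, 256 px / 33.8 um / 3 mm detector, 8 keV,
#' 100 nm focus — rejecting unknown keys (with a spelling suggestion) and
#' non-positive physical quantities before any computation starts.
#'
#' @param raw Named list (e.g. parsed from YAML/JSON), or `NULL` for pure
#'   defaults.  `pulses` may be one pulse set (named list) or a list of sets.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(raw = NULL) {
  cfg <- .default_config()
  if (is.null(raw)) raw <- list()
  .check_known_keys(raw, names(cfg), "config")
  for (sec in names(raw)) {
    if (sec %in% c("seed")) { cfg[[sec]] <- raw[[sec]]; next }
    if (sec == "pulses") next
    .check_known_keys(raw[[sec]], names(cfg[[sec]]), sec)
    cfg[[sec]] <- modifyList(cfg[[sec]], raw[[sec]])
  }
  if (!is.null(raw$pulses)) {
    p <- raw$pulses
    if (!is.null(names(p)) && any(nzchar(names(p)))) p <- list(p)
    pulse_keys <- c("photon_count", "fwhm", "photon_energy", "focus_diameter")
    for (i in seq_along(p)) {
      .check_known_keys(p[[i]], pulse_keys, sprintf("pulses[%d]", i))
      p[[i]] <- modifyList(cfg$pulses[[1]], p[[i]])
    }
    cfg$pulses <- p
  }
  if (!cfg$sample$source %in% c("synthetic", "pdb"))
    stop("sample.source must be 'synthetic' or 'pdb'", call. = FALSE)
  if (cfg$sample$source == "pdb" && is.null(cfg$sample$pdb_path))
    stop("sample.source = 'pdb' requires sample.pdb_path", call. = FALSE)
  .check_positive(cfg, "sample", c("ensemble_size"))
  if (cfg$sample$heterogeneity_rmsd < 0)
    stop("config key sample.heterogeneity_rmsd must be >= 0", call. = FALSE)
  .check_positive(cfg, "detector", c("n_pixels", "pixel_size", "distance"))
  .check_positive(cfg, "dynamics", c("frame_dt", "integrator_dt"))
  for (i in seq_along(cfg$pulses)) {
    for (k in names(cfg$pulses[[i]]))
      if (cfg$pulses[[i]][[k]] <= 0)
        stop(sprintf("config key pulses[%d].%s must be a positive number",
                     i, k), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

# 31-bit polynomial rolling hash over the serialized object; provenance
# fingerprint only
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.pulse_tag <- function(p) sprintf("T%g_Np%.0e", p$fwhm, p$photon_count)

#' Run the full damage-noise pipeline
#'
#' Executes, for each configured pulse set: (1) heterogeneous ensemble
#' generation, (2) stochastic ionization and Coulomb-explosion trajectories
#' (per-explosion seed = master seed + explosion index), (3) instantaneous and
#' time-integrated diffraction patterns, (4) ensemble statistics — masked
#' pixelwise Pearson correlation against the undamaged first-frame mean,
#' resolution-shell profiles with speckle contrast and the three SNRs,
#' per-shell correlations, and heterogeneity / shot-noise baselines.
#' Artifacts (rds arrays, CSV shell tables, JSON summary and manifest) are
#' written under `out_dir`; reruns with the same config reproduce the
#' statistics exactly.
#'
#' @param config A `run_config` from [validate_config()] (or a raw list).
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  seed <- config$seed
  say("[sample] building ensemble (N = %d, target RMSD %.2f A, seed %d)",
      config$sample$ensemble_size, config$sample$heterogeneity_rmsd, seed)
  base <- if (config$sample$source == "pdb") read_pdb(config$sample$pdb_path)
          else generate_lysozyme_like(seed)
  ens <- perturb_ensemble(base, config$sample$ensemble_size,
                          config$sample$heterogeneity_rmsd, seed = seed)
  geom <- detector_geometry(config$detector$n_pixels,
                            config$detector$pixel_size,
                            config$detector$distance,
                            config$pulses[[1]]$photon_energy)
  qm <- build_qmap(geom)
  mask <- config$analysis$mask_cutoff

  summaries <- list()
  artifacts <- character(0)
  for (p in config$pulses) {
    tag <- .pulse_tag(p)
    profile <- pulse_profile(p$photon_count, p$fwhm, p$photon_energy,
                             p$focus_diameter)
    frames <- pulse_frame_times(profile, config$dynamics$frame_dt)
    cache <- new.env(parent = emptyenv())
    integrated <- vector("list", config$sample$ensemble_size)
    firsts <- vector("list", config$sample$ensemble_size)
    say("[%s] %d explosions over [%g, %g] fs", tag,
        config$sample$ensemble_size, min(frames), max(frames))
    for (n in seq_len(config$sample$ensemble_size)) {
      expl_seed <- seed + n
      ion <- sample_ionization(ens$members[[n]], profile, frames,
                               seed = expl_seed)
      traj <- run_explosion(ens$members[[n]], ion,
                            dt = config$dynamics$integrator_dt)
      series <- trajectory_patterns(traj, qm, profile,
                                    mode = config$analysis$mode,
                                    max_nodes = config$analysis$max_nodes,
                                    cache = cache)
      integrated[[n]] <- integrate_time(series)
      firsts[[n]] <- first_frame_pattern(traj, qm, cache)
      say("[%s] explosion %d/%d done (seed %d, final charge %.2f/atom)",
          tag, n, config$sample$ensemble_size, expl_seed,
          mean(ion$charges[, ncol(ion$charges)]))
    }
    est <- ensemble_stats(integrated, mu0 = firsts)
    shells <- snr_profiles(radial_profiles(est))
    pear <- masked_pearson(est$mu, est$mu0, qm, mask)
    shell_r <- shell_pearson(est)
    say("[%s] masked pixelwise r = %.4f", tag, pear$r)
    het <- heterogeneity_baseline(ens, qm, config$analysis$baseline_iterations,
                                  seed = seed, q_cutoff = mask)
    shot <- shot_noise_baseline(ens$members[[1]], qm, profile,
                                config$analysis$baseline_iterations,
                                seed = seed + 1L, q_cutoff = mask)
    shells_file <- file.path(out_dir, sprintf("shells_%s.csv", tag))
    write.csv(shells, shells_file, row.names = FALSE)
    pat_file <- file.path(out_dir, sprintf("patterns_%s.rds", tag))
    saveRDS(list(mu = est$mu, var = est$var, mu0 = est$mu0,
                 integrated = lapply(integrated, `[[`, "intensity")),
            pat_file)
    artifacts <- c(artifacts, shells_file, pat_file)
    out_mask <- shells$q > mask
    summaries[[tag]] <- list(
      pulse = p,
      pixelwise_r = pear$r, pixelwise_p = pear$p_value,
      heterogeneity_baseline = het[c("mean", "sd")],
      shot_noise_baseline = shot[c("mean", "sd")],
      min_shot_to_damage = min((shells$shot / shells$sigma)[out_mask &
                                 shells$sigma > 0], na.rm = TRUE),
      mean_speckle_contrast = mean(shells$sigma_I[out_mask], na.rm = TRUE),
      shell_r_min = min(shell_r$r[shell_r$valid &
                                    shell_r$q > mask], na.rm = TRUE))
  }

  summary_file <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summaries, summary_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "xdn",
    version = as.character(utils::packageVersion("xdn")),
    r_version = R.version.string,
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    config = unclass(config),
    config_hash = .config_hash(unclass(config)),
    seed = seed,
    explosion_seeds = seed + seq_len(config$sample$ensemble_size),
    artifacts = c(basename(artifacts), "summary.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline finished in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}
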