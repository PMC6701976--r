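# Ensemble statistics, correlations, baselines, shells and SNRs.

make_ensemble <- function(mats, qmap, mu0 = NULL) {
  pats <- lapply(mats, function(m) xdn:::.new_pattern(m, qmap))
  ensemble_stats(pats, mu0 = mu0)
}

test_that("ensemble_stats: closed forms and the Poisson variance check", {
  qm <- build_qmap(test_geometry(16L))
  a <- matrix(runif(256), 16)
  one <- make_ensemble(list(a), qm)
  expect_equal(one$mu, a)
  expect_true(all(one$var == 0))
  b <- matrix(runif(256), 16)
  two <- make_ensemble(list(a, b), qm)
  expect_equal(two$mu, (a + b) / 2)
  expect_equal(two$var, (a - b)^2 / 4)  # population (1/N) convention
  expect_error(ensemble_stats(list()), "empty")
  # 100 Poisson samples of a flat mean-50 pattern: pixel-averaged var ~ 50
  set.seed(9)
  flat <- lapply(1:100, function(i) matrix(rpois(256, 50), 16))
  est <- make_ensemble(flat, qm)
  expect_lt(abs(mean(est$var) - 50) / 50, 0.1)
  # one-pass/two-pass variance agreement
  stack <- simplify2array(flat)
  v2 <- apply(stack, c(1, 2), function(x) mean((x - mean(x))^2))
  expect_lt(max(abs(est$var - v2)) / max(v2), 1e-8)
})

test_that("masked_pearson: identities, mask and null distribution", {
  qm <- build_qmap(test_geometry(128L))
  set.seed(4)
  a <- matrix(runif(128^2), 128)
  self <- masked_pearson(a, a, qm)
  expect_equal(self$r, 1)
  anti <- masked_pearson(a, 10 - a, qm)
  expect_equal(anti$r, -1)
  # affine invariance
  expect_equal(masked_pearson(a, 3 * a + 2, qm)$r, 1)
  # mask actually removes the small-q pixels
  expect_identical(self$n_pixels, sum(qm$qmag > 0.65))
  expect_lt(self$n_pixels, 128^2)
  # two independent noise maps: |r| small, p typically large
  b <- matrix(runif(128^2), 128)
  null <- masked_pearson(a, b, qm)
  expect_lt(abs(null$r), 0.05)
  expect_error(masked_pearson(a, matrix(1, 128, 128), qm), "degenerate")
})

test_that("heterogeneity baseline: identical structures, monotone decorrelation", {
  s <- mini_globule(40, 15)
  qm <- build_qmap(test_geometry(24L))
  same <- structure(list(members = replicate(4, s, simplify = FALSE),
                         target_rmsd = 0), class = "structure_ensemble")
  bl <- heterogeneity_baseline(same, qm, iterations = 20, seed = 1)
  expect_true(all(abs(bl$r - 1) < 1e-12))
  means <- vapply(c(0.5, 1.0, 2.0), function(rmsd) {
    ens <- perturb_ensemble(s, 8, rmsd, seed = 5)
    heterogeneity_baseline(ens, qm, iterations = 60, seed = 2)$mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # determinism
  ens <- perturb_ensemble(s, 6, 1, seed = 1)
  b1 <- heterogeneity_baseline(ens, qm, iterations = 30, seed = 3)
  b2 <- heterogeneity_baseline(ens, qm, iterations = 30, seed = 3)
  expect_identical(b1$r, b2$r)
})

test_that("shot-noise baseline rises with intensity towards r = 1", {
  s <- mini_globule(40, 15)
  qm <- build_qmap(test_geometry(24L))
  # x1, x10, x100 pattern scale from a level where the correlation is
  # signal-dominated
  means <- vapply(c(1e13, 1e14, 1e15), function(np) {
    shot_noise_baseline(s, qm, pulse_profile(np, 5), iterations = 40,
                        seed = 1)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  strong <- shot_noise_baseline(s, qm, pulse_profile(1e17, 5),
                                iterations = 10, seed = 1)
  expect_gt(strong$mean, 0.999)
  empty <- atomic_structure("C", matrix(0, 1, 3), core_electrons = 0L,
                            valence_electrons = 0L)
  expect_error(shot_noise_baseline(empty, qm, pulse_profile(1e12, 5)),
               "degenerate")
})

test_that("radial profiles: symmetric, flat and hand-computed cases", {
  qm <- build_qmap(test_geometry(16L))
  idx <- xdn:::.shell_index(qm)
  # shell-constant pattern has zero speckle contrast everywhere
  ring <- matrix(as.numeric(idx), 16)
  est <- make_ensemble(list(ring), qm)
  sh <- radial_profiles(est)
  expect_true(all(sh$sigma_I < 1e-12))
  expect_true(all(sh$sigma == 0))
  # flat pattern: mu(q) = c in every shell
  flat <- make_ensemble(list(matrix(7, 16, 16)), qm)
  expect_true(all(abs(radial_profiles(flat)$mu - 7) < 1e-12))
  # one bright pixel per shell: sigma_I matches direct arithmetic
  bright <- rep(0, 256)
  for (s0 in unique(idx)) bright[which(idx == s0)[1]] <- 5
  estb <- make_ensemble(list(matrix(bright, 16)), qm)
  shb <- radial_profiles(estb)
  for (k in seq_len(nrow(shb))) {
    v <- bright[idx == shb$shell[k]]
    expect_equal(shb$sigma_I[k], sqrt(mean(v^2) - mean(v)^2),
                 tolerance = 1e-12)
  }
  # shot noise column is sqrt of the shell mean
  expect_equal(shb$shot, sqrt(shb$mu))
})

test_that("shell_pearson: identity, affine invariance, degenerate flags", {
  qm <- build_qmap(test_geometry(16L))
  set.seed(2)
  mu <- matrix(runif(256), 16)
  est <- make_ensemble(list(mu), qm, mu0 = xdn:::.new_pattern(mu, qm))
  sp <- shell_pearson(est)
  expect_true(all(abs(sp$r[sp$valid] - 1) < 1e-12))
  est2 <- make_ensemble(list(2 * mu + 5), qm,
                        mu0 = xdn:::.new_pattern(mu, qm))
  sp2 <- shell_pearson(est2)
  expect_true(all(abs(sp2$r[sp2$valid] - 1) < 1e-12))
  # radially symmetric reference: zero shell variance flagged, not zeroed
  ring <- matrix(as.numeric(xdn:::.shell_index(qm)), 16)
  est3 <- make_ensemble(list(mu), qm, mu0 = xdn:::.new_pattern(ring, qm))
  sp3 <- shell_pearson(est3)
  expect_true(any(!sp3$valid))
  expect_true(all(is.na(sp3$r[!sp3$valid])))
  expect_error(shell_pearson(make_ensemble(list(mu), qm)), "mu0")
})

test_that("snr_profiles arithmetic and edge cases", {
  sh <- data.frame(shell = 1:4, q = 1:4, resolution = 10 / (1:4),
                   n_pixels = 10, mu = c(4, 4, 0, 4),
                   sigma = c(1, 0, 0, 2), shot = sqrt(c(4, 4, 0, 4)),
                   sigma_I = c(6, 6, 0, 0))
  out <- snr_profiles(sh)
  # mu = 4, sigma = 1, sigma_I = 6 -> SNRs 3, 6, 2
  expect_equal(out$snr_shot[1], 3)
  expect_equal(out$snr_damage[1], 6)
  expect_equal(out$snr_total[1], 2)
  # sigma = 0: total reduces to the shot-noise SNR
  expect_equal(out$snr_total[2], out$snr_shot[2])
  # zero signal: all SNRs are zero
  expect_equal(unlist(out[4, c("snr_shot", "snr_damage", "snr_total")]),
               c(snr_shot = 0, snr_damage = 0, snr_total = 0))
  # zero denominators with nonzero signal are flagged NA, never Inf
  sh$sigma_I[3] <- 1
  out2 <- snr_profiles(sh)
  expect_true(is.na(out2$snr_shot[3]))
  expect_false(any(is.infinite(unlist(out2[c("snr_shot", "snr_damage",
                                             "snr_total")]))))
  # SNR_tot <= min(SNR_S, SNR_D) wherever defined
  ok <- !is.na(out2$snr_total) & !is.na(out2$snr_damage)
  expect_true(all(out2$snr_total[ok] <=
                    pmin(out2$snr_shot[ok], out2$snr_damage[ok]) + 1e-12))
})

test_that("no-damage limit: identical frozen structures give r = 1 and zero damage noise", {
  s <- mini_globule(20, 8)
  qm <- build_qmap(test_geometry(16L))
  prof <- pulse_profile(1e12, 5)
  quiet <- constant_ionization(s, 0L, pulse_frame_times(prof))
  froz <- frozen_trajectory(s, quiet)
  ser <- trajectory_patterns(froz, qm, prof, "full", max_nodes = 8L)
  ints <- replicate(4, integrate_time(ser), simplify = FALSE)
  firsts <- replicate(4, first_frame_pattern(froz, qm), simplify = FALSE)
  est <- ensemble_stats(ints, mu0 = firsts)
  expect_lt(max(est$var), (1e-12 * max(est$mu))^2)  # zero up to rounding
  sh <- snr_profiles(radial_profiles(est))
  expect_lt(max(sh$sigma), 1e-12 * max(sh$mu))
  expect_equal(masked_pearson(est$mu, est$mu0, qm)$r, 1, tolerance = 1e-9)
})

test_that("gating: no-damage control accumulates without post-peak decline", {
  s <- mini_globule(20, 8)
  qm <- build_qmap(test_geometry(16L))
  prof <- pulse_profile(1e12, 5)
  ens <- perturb_ensemble(s, 3, 0.5, seed = 1)
  series <- lapply(ens$members, function(m) {
    froz <- frozen_trajectory(m, constant_ionization(m, 0L,
                                                     pulse_frame_times(prof)))
    trajectory_patterns(froz, qm, prof, "full", max_nodes = 12L)
  })
  g <- gating_curve(series, shell_resolution = 5)
  good <- !is.na(g$snr_total)
  expect_gt(sum(good), 5)
  v <- g$snr_total[good]
  # monotone accumulation up to numerical noise, no decline after the peak
  expect_true(all(diff(v) > -1e-9))
  expect_error(gating_curve(series[1]), "at least 2")
})

test_that("averaging 16 patterns closes a 4-fold SNR gap", {
  expect_identical(averaging_factor(4), 16)
  # empirical sqrt(N) law: residual noise of N-pattern averages
  set.seed(8)
  lam <- matrix(60, 40, 40)
  resid_rms <- function(n) {
    avg <- Reduce(`+`, lapply(seq_len(n), function(i)
      matrix(rpois(1600, lam), 40))) / n
    sqrt(mean((avg - lam)^2))
  }
  expect_equal(resid_rms(1) / resid_rms(16), 4, tolerance = 0.2)
})
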