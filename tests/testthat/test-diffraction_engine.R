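# Detector geometry, ionic form factors and pattern computation.

test_that("default geometry spans the reference resolution range", {
  geom <- detector_geometry()
  qm <- build_qmap(geom)
  lambda <- pulse_wavelength(8)
  # extreme corner of the detector face: 128 px * 33.8 um from the centre
  half <- 128 * 33.8e-3
  corner_q <- 2 * sin(atan(sqrt(2) * half / 3) / 2) / lambda
  expect_equal(10 / corner_q, 1.46, tolerance = 0.005)  # Angstrom
  # outermost pixel centre is just inside that
  expect_lt(10 / max(qm$qmag), 1.48)
  # q = 0.5 nm^-1 is 20 A, the mask floor 0.65 nm^-1 is ~15 A
  expect_equal(10 / 0.5, 20)
  expect_equal(10 / 0.65, 15.4, tolerance = 0.01)
  # centre pixels see essentially forward scattering
  expect_lt(min(qm$qmag), 0.35)
  # q increases with distance from the beam centre along a row
  n <- geom$n_pixels
  mid <- matrix(qm$qmag, n, n)[, n / 2]
  expect_true(all(diff(mid[(n / 2 + 1):n]) > 0))
  # corner and centre bracket everything
  expect_identical(max(qm$qmag), matrix(qm$qmag, n, n)[1, 1])
})

test_that("x10-scaled geometry has matching corner q (effective pixels)", {
  q_corner <- function(g) max(build_qmap(g)$qmag)
  q1 <- q_corner(detector_geometry(256L, 33.8, 3))
  q10 <- q_corner(detector_geometry(1024L, 84.5, 30))
  expect_lt(abs(q10 - q1) / q1, 0.005)
})

test_that("ionic form factors: electron counts, positivity, tabulated check", {
  # f(0) equals the bound-electron count
  expect_equal(ionic_form_factor("C", 0, 4, 0), 6)
  expect_equal(ionic_form_factor("C", 1, 3, 0), 4)
  expect_equal(ionic_form_factor("S", 0, 14, 0), 16)
  expect_equal(ionic_form_factor("H", 0, 1, 0), 1)
  expect_equal(ionic_form_factor("H", 0, 0, 0.5), 0)
  expect_error(ionic_form_factor("C", 3, 4, 0), "core")
  q <- seq(0, 7, by = 0.05)  # nm^-1, full detector range
  for (el in c("H", "C", "N", "O", "S")) {
    gs <- ground_state_electrons(el)
    # neutral atoms match the standard tables to well under 3%
    f <- ionic_form_factor(el, 0, gs$valence, q)
    ref <- it92_ff(el, q)
    expect_lt(max(abs(f - ref) / ref), 0.03)
    # positive and non-increasing on the detector range, also for ions
    for (state in list(c(0, gs$valence),
                       c(min(1, gs$core), max(gs$valence - 1, 0)))) {
      fi <- ionic_form_factor(el, state[1], state[2], q)
      expect_true(all(fi >= 0))
      expect_true(all(diff(fi) <= 1e-12))
    }
  }
  # neutral O at q = 2 nm^-1 within 3% of the standard value
  expect_lt(abs(ionic_form_factor("O", 0, 6, 2) - it92_ff("O", 2)) /
              it92_ff("O", 2), 0.03)
  # losing electrons lowers f everywhere (ionization transparency)
  expect_true(all(ionic_form_factor("C", 0, 3, q) <
                    ionic_form_factor("C", 0, 4, q)))
})

test_that("single-atom and two-atom patterns match closed forms", {
  qm <- build_qmap(test_geometry(32L))
  one <- atomic_structure("C", matrix(0, 1, 3))
  flu <- 3e7
  pat <- pattern_instantaneous(one, qm, flu)
  f_c <- ionic_form_factor("C", 0, 4, qm$qmag)
  expect_equal(as.vector(pat$intensity), qm$prefactor * flu * f_c^2,
               tolerance = 1e-12)
  # two identical atoms d apart along x: fringes cos^2(pi qx d)
  d <- 0.5
  two <- atomic_structure(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  pat2 <- pattern_instantaneous(two, qm, flu)
  expect_equal(as.vector(pat2$intensity),
               qm$prefactor * flu * 4 * f_c^2 * cos(pi * qm$qx * d)^2,
               tolerance = 1e-10)
  # first fringe zero at qx = 1/(2d)
  i0 <- which.min(abs(qm$qx - 1 / (2 * d)))
  expect_lt(pat2$intensity[i0] / max(pat2$intensity), 1e-3)
})

test_that("coherent sum equals the brute-force pairwise oracle", {
  qm <- build_qmap(test_geometry(16L))
  set.seed(42)
  for (m in c(3L, 10L)) {
    el <- sample(c("C", "N", "O", "S", "H"), m, replace = TRUE)
    gs <- ground_state_electrons(el)
    frame <- atomic_structure(el, matrix(runif(3 * m, -1, 1), m, 3),
                              core_electrons = pmax(gs$core -
                                rbinom(m, 1, 0.3), 0),
                              valence_electrons = pmax(gs$valence -
                                rbinom(m, 2, 0.3), 0))
    pat <- pattern_instantaneous(frame, qm, 2.5)
    oracle <- pairwise_pattern_oracle(frame, qm, 2.5)
    expect_lt(max(abs(pat$intensity - oracle)) / max(oracle), 1e-10)
  }
})

test_that("forward intensity follows the total-electron sum rule", {
  geom <- detector_geometry(64L, 33.8, 30)  # small angles only
  qm <- build_qmap(geom)
  s <- mini_globule(20, 10)
  pat <- pattern_instantaneous(s, qm, 1)
  i0 <- which.min(qm$qmag)
  n_el <- sum(ground_state_electrons(s$elements)$z)
  expect_equal(pat$intensity[i0] / (qm$prefactor[i0]), n_el^2,
               tolerance = 0.02)
})

test_that("patterns are linear in fluence and decrease under ionization", {
  qm <- build_qmap(test_geometry(16L))
  s <- mini_globule(15, 5)
  p1 <- pattern_instantaneous(s, qm, 1e6)
  p2 <- pattern_instantaneous(s, qm, 2e6)
  expect_equal(p2$intensity, 2 * p1$intensity, tolerance = 1e-12)
  # uniformly reduced form factors lower every pixel (the electron-loss
  # bound): scaling all f by c scales the whole pattern by c^2
  scaled <- pairwise_pattern_oracle(s, qm, 1e6)
  expect_true(all(0.64 * scaled <= p1$intensity + 1e-15))
  # and the forward (q -> 0) intensity always drops when electrons are lost
  gs <- ground_state_electrons(s$elements)
  ion <- atomic_structure(s$elements, s$positions,
                          core_electrons = gs$core,
                          valence_electrons = pmax(gs$valence - 1L, 0L))
  pi1 <- pattern_instantaneous(ion, qm, 1e6)
  i0 <- which.min(qm$qmag)
  expect_lt(pi1$intensity[i0], p1$intensity[i0])
})

test_that("time integration, partial integration and modes behave", {
  qm <- build_qmap(test_geometry(16L))
  s <- mini_globule(15, 5)
  prof <- pulse_profile(1e12, 5)
  ion <- sample_ionization(s, prof, seed = 2)
  traj <- run_explosion(s, ion)
  ser <- trajectory_patterns(traj, qm, prof, "full", max_nodes = 16L)
  expect_error(integrate_time(list()), "empty")
  one <- integrate_time(ser[1])
  expect_equal(one$intensity, ser[[1]]$intensity)
  twice <- integrate_time(list(ser[[1]], ser[[1]]))
  expect_equal(twice$intensity, 2 * ser[[1]]$intensity)
  # total fluence in the series matches the pulse over the window
  area <- focal_area(prof)
  expect_equal(sum(vapply(ser, `[[`, numeric(1), "fluence")) * area,
               1e12, tolerance = 0.005)
  # partial integration: last-cut equals full, pixelwise non-decreasing
  full <- integrate_time(ser)
  expect_equal(partial_integrate(ser, max(traj$frame_times))$intensity,
               full$intensity)
  cuts <- c(-20, -2, 0, 2, 10)
  prev <- partial_integrate(ser, cuts[1])$intensity
  for (tc in cuts[-1]) {
    cur <- partial_integrate(ser, tc)$intensity
    expect_true(all(cur - prev >= -1e-12))
    prev <- cur
  }
  expect_true(all(partial_integrate(ser, -100)$intensity == 0))

  # frozen trajectory: ionization_only coincides with full mode
  froz <- frozen_trajectory(s, ion)
  a <- integrate_time(trajectory_patterns(froz, qm, prof, "full",
                                          max_nodes = 8L))
  b <- integrate_time(trajectory_patterns(froz, qm, prof, "ionization_only",
                                          max_nodes = 8L))
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  # displacement_only keeps all electrons: more photons than full mode
  late <- length(ser)
  d_only <- trajectory_patterns(traj, qm, prof, "displacement_only",
                                max_nodes = 16L)
  expect_gt(sum(d_only[[late]]$intensity), sum(ser[[late]]$intensity))
  expect_error(trajectory_patterns(traj, qm, prof, "nonsense"), "arg")
})

test_that("frozen un-ionized integration equals single frame times fluence", {
  qm <- build_qmap(test_geometry(16L))
  s <- mini_globule(12, 6)
  prof <- pulse_profile(1e12, 5)
  quiet <- constant_ionization(s, 0L, pulse_frame_times(prof))
  froz <- frozen_trajectory(s, quiet)
  ser <- trajectory_patterns(froz, qm, prof, "full", max_nodes = 41L)
  unit <- pattern_instantaneous(s, qm, 1)
  total_flu <- sum(vapply(ser, `[[`, numeric(1), "fluence"))
  expect_equal(integrate_time(ser)$intensity, unit$intensity * total_flu,
               tolerance = 1e-6)
  # symmetric no-damage series: centre cut gives half the total, up to the
  # half-bin discretization of the 0.5 fs frames
  half <- partial_integrate(ser, 0)
  expect_lt(abs(sum(half$intensity) / sum(integrate_time(ser)$intensity) -
                  0.5), 0.05)
})

test_that("x10 detector binned 4x reproduces default shell means within 1%", {
  # a sparse sample with the reference 3.2 nm extent, so the speckle scale
  # relative to the pixels matches the study conditions
  set.seed(5)
  s <- atomic_structure(sample(c("C", "N", "O", "S"), 12, TRUE),
                        matrix(rnorm(36, 0, 0.8), 12, 3))
  pb <- pattern_instantaneous(s, detector_geometry(1024L, 84.5, 30),
                              1e8)$intensity
  ps <- pattern_instantaneous(s, detector_geometry(256L, 33.8, 3),
                              1e8)$intensity
  binned <- matrix(0, 256, 256)
  for (i in 1:4) for (j in 1:4)
    binned <- binned + pb[seq(i, 1024, by = 4), seq(j, 1024, by = 4)]
  qm <- build_qmap(detector_geometry(256L, 33.8, 3))
  idx <- xdn:::.shell_index(qm)
  mu_s <- tapply(as.vector(ps), idx, mean)
  mu_b <- tapply(as.vector(binned), idx, mean)
  qsh <- tapply(qm$qmag, idx, mean)
  # analysis shells (outside the central-speckle mask) agree within 1%
  sel <- qsh > 0.65
  expect_lt(max(abs(mu_b[sel] - mu_s[sel]) / mu_s[sel]), 0.01)
})
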