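# xdn — radiation-damage noise in XFEL single-particle diffraction

X-ray free-electron lasers can, in principle, image single biomolecules at
atomic resolution: one femtosecond pulse, one diffraction pattern, no
crystal. The pulse also ionizes the sample and blows it apart by Coulomb
repulsion, and the long-standing assumption is that this radiation damage is
what limits the achievable resolution. `xdn` is a simulation and analysis
package for asking that question quantitatively: it simulates the ionization
and explosion of a lysozyme-sized protein during pulses of 5–50 fs with
10^12–10^13 photons, computes the time-integrated diffraction each exploding
copy would produce, and compares the *damage noise* (shot-to-shot variance
caused by stochastic ionization and ionic motion) against photon shot noise
and sample heterogeneity. It is aimed at structural biologists and XFEL
methods developers who want a desk-scale, fully scriptable model of the
damage–signal trade-off.

## The model

For explosion *n*, the expected photon count in detector pixel **q** at
frame time *t_f* is

    I_n(q, t_f) = r_e^2 P(q) dΩ I(t_f) | Σ_i f_i(q, t_f) exp(2πi q·R_i(t_f)) |^2

with `|q| = 2 sin θ / λ` (resolution `1/q`), polarization `P`, solid angle
`dΩ`, per-frame fluence `I(t_f)` from a Gaussian pulse
`G(t) = (2 N_p/T) sqrt(ln2/π) exp(−4 ln2 t²/T²)`, and ionic form factors
`f_i` from Slater orbitals that shrink as atoms lose electrons. Frames are
0.5 fs apart; summing them gives the time-integrated pattern `I_n(q)` a real
detector would record. Over an ensemble of `N` explosions the package forms
the pixel mean `μ(q)`, its population variance `σ²(q)`, the undamaged
first-frame mean `μ0(q)`, and per resolution shell (one-pixel annuli):

* speckle contrast `σ_I(q)` — the shell standard deviation of `μ(q)`,
  i.e. the imaging signal;
* shot noise `sqrt(μ(q))` and damage noise `σ(q)`;
* `SNR_S = σ_I/sqrt(μ)`, `SNR_D = σ_I/σ`,
  `SNR_tot = σ_I/(sqrt(μ)+σ)`;
* masked Pearson correlations (central speckle `q ≤ 0.65 nm⁻¹` excluded)
  between damaged and undamaged means, with heterogeneity and shot-noise
  baselines;
* SNR accumulation ("gating") curves from partial time integration.

Upstream of the diffraction sit a stochastic photoionization + Auger model
(tabulated shell cross sections, element-specific core-hole lifetimes, at
most two core electrons per atom) and a charged-particle Coulomb-explosion
surrogate (velocity-Verlet at 0.05 fs, breakable harmonic bonds, short-range
repulsion) driven by the sampled per-atom charge histories.

## Worked example

One explosion of the synthetic lysozyme-like sample (composition
C613 H959 N193 O185 S10) under a 5 fs, 10^12-photon, 8 keV pulse:

```r
library(xdn)
sample <- generate_lysozyme_like(seed = 1)
pulse  <- pulse_profile(1e12, fwhm = 5)     # photons, fs; 8 keV, 100 nm focus
ion    <- sample_ionization(sample, pulse, seed = 42)
traj   <- run_explosion(sample, ion)
geom   <- detector_geometry(64, 135.2)      # 64 x 64 binning of the 256 px face
qmap   <- build_qmap(geom)
series     <- trajectory_patterns(traj, qmap, pulse)
integrated <- integrate_time(series)
undamaged  <- first_frame_pattern(traj, qmap)
masked_pearson(integrated, undamaged, qmap)
```

which prints

```
ionization_trajectory: 1960 atoms, 41 frames [-10, 10] fs, mean final charge 1.098
damage_trajectory: 1960 atoms, 41 frames [-10, 10] fs, Rg 1.228 -> 1.619 nm
diffraction_pattern: 64 x 64 px, integrated, total 188.1 photons (t = 9.5 fs)
masked Pearson r = 0.9753 (p = 0, 4080 pixels, q > 0.65 nm^-1)
```

Read: the pulse strips about 1.1 electrons per atom, the radius of gyration
grows from 1.23 to 1.62 nm by +10 fs (the explosion is under way), the
detector collects ~190 scattered photons, and the time-integrated pattern
still correlates at r = 0.975 with the undamaged one outside the central
speckle — the speckles survive the explosion.

Full ensemble runs (many explosions, all statistics, CSV/JSON artifacts) go
through a config:

```r
cfg <- validate_config(list(sample = list(ensemble_size = 20),
                            pulses = list(photon_count = 1e12, fwhm = 50)))
run_pipeline(cfg, "results/")
```

or equivalently the CLI: `inst/cli/xdn all --config run.yaml --out results/`.

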