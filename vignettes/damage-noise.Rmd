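---
title: "Damage noise in XFEL single-particle diffraction: model and methods"
author: "xdn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damage noise in XFEL single-particle diffraction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xdn)
```

`xdn` asks a single quantitative question: when a femtosecond X-ray pulse
ionizes a protein-sized particle and blows it apart, how much of the damage
shows up as *noise* in the recorded diffraction pattern, and how does that
noise compare with the two noise sources an experiment cannot avoid — photon
shot noise and conformational heterogeneity of the injected sample? This
vignette documents the model, its parameters and their defaults, the
numerical choices, and the deliberate reductions in scale, so that a reader
can judge exactly what the package's tests do and do not demonstrate.

## The simulated experiment

One "shot" is simulated in four stages:

1. **Sample.** A 1960-atom structure with the hen egg-white lysozyme
   composition C613 H959 N193 O185 S10, either read from a PDB file or
   generated as a compact self-avoiding globule at protein density
   (`generate_lysozyme_like()`). An ensemble of starting structures with a
   calibrated mean pairwise heavy-atom RMSD (default 0.95 Å) emulates sample
   heterogeneity.
2. **Ionization.** Each atom carries at most two core (K-shell) electrons
   plus a valence pool. Per 0.5 fs step, core and valence photoionization
   events are drawn from Poisson rates `σ_shell × fluence`; every core hole
   schedules an Auger decay after an exponential delay, which refills the
   hole from the valence pool and ejects a second valence electron (net +1).
   Cross sections of photoionized atoms are rescaled by the remaining
   electron fraction per shell, so heavily stripped atoms become
   transparent.
3. **Explosion.** The accumulated charges drive a charged-particle dynamics
   surrogate: pairwise Coulomb repulsion, harmonic bonds (inferred from the
   starting geometry) that sever permanently beyond 1.5 of their rest
   length, and a steep `r^-12` contact repulsion, integrated by
   velocity-Verlet at 0.05 fs from rest.
4. **Diffraction and statistics.** Every 0.5 fs frame yields an
   instantaneous pattern
   `I(q) = r_e² P(q) dΩ F |Σ_i f_i(q) e^{2πi q·R_i}|²` in expected-photon
   units; their fluence-weighted sum is the time-integrated pattern. Over
   `N` explosions the package computes pixel means and population variances,
   the undamaged first-frame mean, masked Pearson correlations with
   heterogeneity and shot-noise baselines, resolution-shell profiles,
   speckle contrast, the three SNRs, and SNR-accumulation (gating) curves
   from partial time integration. Three damage modes separate the
   mechanisms: `full`, `ionization_only` (atoms frozen) and
   `displacement_only` (ground-state form factors).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| photon count `N_p` | 1e12 (also 1e13) | photons | current-facility vs. next-generation intensity |
| pulse FWHM `T` | 5 / 25 / 50 | fs | the short-to-long pulse comparison at 8 keV |
| photon energy | 8 | keV | typical imaging beamline; λ = 0.155 nm |
| focus diameter | 100 | nm | photons spatially uniform over the focus |
| detector | 256 px of 33.8 µm at 3 mm | — | spans ~15 Å (central-speckle edge) to ~1.46 Å (corner) |
| frame spacing | 0.5 | fs | granularity of charge states and patterns |
| integrator step | 0.05 | fs | conserves energy to <0.5% over 200 fs at frozen charges |
| heterogeneity RMSD | 0.95 | Å | calibrated conformational spread of the starting ensemble |
| mask cutoff | 0.65 | nm⁻¹ | removes the central speckle (>15 Å), which overlaps the beam |
| ensemble size `N` | 20 | — | desk-scale default (see below) |
| Coulomb constant | 1.4400 | eV·nm | `e²/4πε₀` |
| bond constant / break | 30 eV/nm², 1.5·r₀ | — | breakable-bond stand-in for anharmonic bonds |
| Auger lifetimes | C 10.7, N 7.1, O 4.9, S 1.3 | fs | literature K-hole 1/e lifetimes; H has no Auger channel |

Cross sections ship in `inst/extdata/photoabsorption.csv` (Cromer–Liberman
f″, converted by `σ = 2 r_e λ f″`, with provenance in the file header).
The K-shell/valence split is an edge-jump estimate (C/N 0.95, O 0.94,
S 0.87); hydrogen's single electron counts as valence, giving it no Auger
channel and a vanishing cross section at 8 keV (~1e-12 nm², i.e. about
10⁻⁴ events per pulse — hydrogens stay neutral and this is why only ~1000
of the 1960 atoms ever charge).

## Form factors

Ionic scattering factors are analytic Fourier transforms of single-zeta
Slater orbitals, so `f(0)` equals the bound-electron count exactly for every
ionization state. The 1s exponents are Clementi–Raimondi values; valence
exponents were refined once against the standard IT92 neutral-atom tables
over the detector's q range, after which the worst neutral-atom deviation is
0.32% (the package asserts ≤3%). Two consequences worth knowing:

* the tabulated "H" of the standard tables is the *bonded* (contracted)
  hydrogen; the package follows it (ζ = 1.16) rather than the free atom;
* ionization re-screens the remaining shells via Slater's rules, so an
  ion's `f(q)` can slightly *exceed* the neutral value at high q even
  though `f(0)` drops — the electron-loss bound is on forward scattering,
  not pixelwise.

## Geometry conventions

`|q| = 2 sin θ_s / λ` without a 2π factor and resolution `1/q`; this is
forced by the detector-corner figure (1.46 Å) and the `cos(2π q·ΔR)` phase
convention of the intensity formula. Polarization is
`P = 1 − sin²(2θ_s) cos²(φ)` for horizontal linear polarization; the solid
angle of a flat-detector pixel is `(p/L)² cos³(2θ_s)`. The beam centre sits
between the four central pixels; pixel q is evaluated at the pixel centre.
The ×10-scaled geometry (1024 px of 84.5 µm at 30 mm) reproduces the
default-geometry shell means within 1% after 4× binning on the analysis
shells — the "effective pixels" equivalence — but not inside the central
speckle, where intensity varies strongly within one effective pixel.

## Numerical choices

* **Simulation window.** Each pulse is simulated over its support
  `[−2T, +2T]` (≥ 99.999% of photons; at least ±10 fs). For the 50 fs pulse
  this is the full ±100 fs window; for shorter pulses the trailing empty
  window adds no fluence and hence no pattern weight, so it is not
  simulated.
* **Quadrature over frames.** Time-integrated patterns group consecutive
  0.5 fs frames into at most 32 bins per explosion, each evaluated at its
  middle frame and weighted with the bin's exact integrated fluence; the
  photon budget is preserved to machine precision and the binning error is
  far below the ensemble noise at these N.
* **Variance convention.** Population (1/N) variances throughout, matching
  the ensemble-statistics definitions; damage noise with N = 1 is exactly
  zero.
* **Shell binning.** One-pixel-wide integer-radius annuli about the beam
  centre. Shells with fewer than 3 pixels, or zero variance on either side
  of a correlation, are flagged invalid rather than silently zeroed, and
  zero-denominator SNRs are `NA`, never `Inf`, so shell indices stay
  aligned across damage modes.
* **Degenerate inputs.** Zero-variance correlation inputs raise an error
  naming the degeneracy; a partial integration cut before the first frame
  returns a valid all-zero pattern.
* **Softening and stability.** Coulomb separations are clamped below
  0.05 nm; the integrator aborts with advice if any atom moves more than
  1 nm in a single step. With all charges frozen, total energy is conserved
  to better than 0.5% over 200 fs; a two-ion system tracks its analytic
  conserved energy to 0.1%.
* **Determinism.** Every stochastic stage takes an explicit seed;
  per-explosion seeds are `master seed + explosion index`. Reruns reproduce
  all statistics bit-identically.

## The synthetic sample: what it does and does not emulate

The generator reproduces the composition, size (3.3 nm diameter, under the
10 nm electron mean-free-path scale that justifies neglecting secondary
ionization), protein-like atomic density, covalent-distance bonding and
explicit hydrogens of the real protein. It does *not* reproduce secondary
structure, side-chain chemistry or a realistic bond topology — the chain is
geometric, not chemical. Heterogeneity is emulated by smooth correlated
displacement fields (a sum of random long-wavelength plane-wave modes,
rescaled so the ensemble hits the target mean pairwise RMSD exactly), not by
thermal sampling of a force field; local geometry is preserved, which is the
property the diffraction statistics care about. Consequently, passing tests
demonstrate the damage-vs-noise *statistics* of a lysozyme-like particle,
not the explosion pathway of any particular protein conformation.

RMSDs are computed **without** rigid-body superposition: all simulated
samples share one laboratory orientation, so rigid displacement components
are diffraction-relevant signal, and fitting them away would understate the
heterogeneity the detector sees. A `superpose` flag exists for comparison.

## The explosion surrogate

The dynamics deliberately keep only what the downstream statistics consume —
displacement magnitudes and their shot-to-shot spread. Compared to an
all-atom force field: bonds are harmonic-until-broken rather than
anharmonic, there are no angle/torsion/attractive terms, atoms start at rest
(the heterogeneous ensemble carries structural variation instead of thermal
velocities), and there is no free-electron screening — the explosion is a
worst case, faster and more violent than a screened one. Quantities that
depend on fine explosion detail therefore carry wide tolerances in the
acceptance checks, while ionization-only and geometry quantities are tight.

## Desk-scale problem sizes

The package's reference analyses run on one CPU in minutes, at sizes chosen
once and used consistently: N = 20 explosions per pulse set (not 150), a
64 × 64 binning of the 256-pixel detector face for ensemble runs, 500
baseline iterations (not 50 000), and ≤32 quadrature bins per explosion
(24 for the native-pixel recomputation below).

One statistic must not be read off the binned detector: the shot-to-damage
noise ratio `sqrt(μ(q))/σ(q)`. Binning by `b × b` pixels multiplies both
`μ` and `σ` by roughly `b²` but the shot noise only by `b`, so the ratio
shrinks by about `b`. The reference value ("shot noise dominates damage
noise by at least a factor 10") refers to the native 33.8 µm pixels, and
the package's acceptance checks therefore recompute that one quantity on
the native 256-pixel geometry from the same explosions (the binned ratio is
roughly 4× smaller, as the scaling argument predicts). Correlations and
contrast ratios are scale-robust and are evaluated on the binned
detector.
At these sizes the ensemble estimates of `σ(q)` and the pixelwise
correlation are noisy at the few-percent level, which is why the
reduced-scale acceptance checks use correspondingly wide bands. The
statistics themselves are unbiased; nothing in the pipeline changes with
scale except estimator variance.

## Known limitations

* No secondary electron-impact ionization, free-electron screening, Compton
  or free-electron scattering; these are the stated approximations of the
  worst-case model, acceptable for samples below the ~10 nm electron
  mean-free-path scale.
* The ionization model's shell partition and Auger lifetimes are literature
  constants, not fitted; different tabulations shift mean end-of-pulse
  charges by a few percent.
* Orientation recovery and 3D merging are out of scope; all patterns share
  one sample orientation.
* The PDB reader supports the five modelled elements only and ignores
  occupancy/B-factors.
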