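---
title: "Quantizing nuclear motion for hydrated-electron absorption spectra"
author: "espec package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantizing nuclear motion for hydrated-electron absorption spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The optical absorption spectrum of an excess electron in water — a
hydrated electron in the bulk, or its embryonic form in a water cluster
anion — is shaped by nuclear motion.  Classical molecular dynamics
samples that motion with Boltzmann statistics but no zero-point energy;
the high-frequency OH stretches, whose quanta (≈0.46 eV at 3700 cm⁻¹)
far exceed k~B~T, are therefore sampled with amplitudes that are much
too small.  Because the electron's binding energy responds strongly to
the OH bond lengths pointing into its cavity, this classical
undersampling narrows and shifts the computed spectrum.

`espec` implements a "two-in-one" route around this:

1. **Mixed quantum–classical dynamics (QCMD).**  One quantum electron is
   represented by its wavefunction on a cubic grid; the water bath is
   classical (a flexible simple point-charge model).  The electron–water
   coupling is a smooth pseudopotential; nuclei move adiabatically on
   the electronic ground-state surface under the classical force plus
   the Hellmann–Feynman force, integrated with velocity Verlet at
   0.5 fs.
2. **Post-hoc quantization of the nuclear trajectory (GSTA).**  The
   classical coordinates x(t) are convolved with a symmetric kernel g
   whose frequency-domain gain is √w(ν), where
   w(ν) = (hν/2k~B~T)·coth(hν/2k~B~T)
   is the ratio of the quantum to the classical mean energy of a
   harmonic oscillator at temperature T.  Low-frequency motion passes
   unchanged (w→1); the amplitude of high-frequency vibrations is
   boosted by √w, so their variances — quadratic observables — carry the
   full quantum factor w, including zero-point motion.
3. **Spectra in the slow-modulation limit.**  For each stored
   configuration the lowest K+1 electronic states are solved on a finer
   grid; each transition deposits its oscillator strength
   f~k~ = 2m~e~ΔE~k~|μ~k0~|²/(3ħ²) at its transition energy ΔE~k~.
   Averaging over configurations gives the ensemble spectrum as an
   oscillator-strength density; the classical and the quantized
   trajectory give paired ensembles that are compared statistically.

The central claim this workflow probes: quantizing nuclear motion
broadens the OH-distance distribution, which broadens (and slightly
red-shifts) the absorption spectrum — and the effect is resolvable as
statistically significant with paired configurations.

## Model components and their knobs

### Units

All interfaces use Å, fs, eV, K, elementary charges.  `especConstants`
holds ħ = 0.65821 eV·fs, k~B~ = 8.6173×10⁻⁵ eV/K, m~e~ = 0.056856
eV·fs²/Å², and the Coulomb constant e²/4πε₀ = 14.3996 eV·Å.  In these
units hν/k~B~T for a 3700 cm⁻¹ mode at 300 K is 17.74.

### Water model

A flexible simple point-charge parameterization
(`inst/extdata/water_spcflex.yaml`): harmonic OH stretch
(k = 45.93 eV/Å², r₀ = 1.012 Å, giving a ≈3600 cm⁻¹ fundamental),
harmonic HOH bend, SPC charges (−0.82/+0.41 e), O–O Lennard-Jones.
In periodic (bulk) runs, intermolecular terms are cut off at
r~c~ = 9 Å through a switching function on [r~c~−1, r~c~] Å.  We use a
*quintic* smoothstep (C²) rather than a cubic Hermite switch: velocity
Verlet's long-time energy conservation is sensitive to force-derivative
discontinuities, and with the C¹ cubic switch the microcanonical drift
of desk-scale runs sat above 10⁻⁴ eV/ps; the C² switch removes most of
that noise.  Isolated clusters interact at full range (the engine lifts
the cutoff to 50 Å when no box is present): the spherical cutoff is a
periodic-box device, and molecules wandering through the taper region
of a small cluster were the residual drift source after the C² fix.
Taper continuity is machine-checked in the tests.

### Electron–water pseudopotential

Each site contributes
V(r) = −k~c~ q erf(A r)/r + Σ~i~ B~i~ exp(−C~i~ r²):
a screened Coulomb term matching the water model's partial charges at
long range plus short-range Gaussian repulsion.  The shipped parameter
file is **synthetic**: it realizes this standard functional form with
constants chosen once so that an idealized six-water cavity binds the
electron (E₀ ≈ −0.6 eV, s→p gaps ≈ 0.6 eV, r~g~ ≈ 3 Å — magnitudes
appropriate for small cluster anions).  It is not a transcription of any
published electron–water parameter table, and all eigensolver,
force-consistency and filter tests are deliberately parameter-agnostic.
Full-scale literature observables (bulk E₀ ≈ −3 eV, 1.72 eV absorption
maximum) are *not* reproduced by this parameter set and are not claimed.

### Grid eigensolver

The kinetic operator is applied spectrally (FFT) on the periodic cube —
the natural discretization for a plane-wave-consistent grid; the
potential is diagonal.  Eigenpairs come from a block Lanczos /
Rayleigh–Ritz iteration with full reorthogonalization, thick restarts,
Davidson-style kinetic preconditioning of the residual expansion
(1/(T~k~+τ) in Fourier space), and deterministic hashed start vectors so
reruns are bit-stable.  Blocks of ≥4 resolve the near-degenerate p
manifold.  Residual tolerances: 10⁻⁹ during dynamics — at 10⁻⁸ the
warm-started ground state lags the nuclei enough to produce a
detectable spurious energy drift (~10⁻³ eV/ps) — and 10⁻⁸ for spectral
solves, where accuracy is limited by statistics, not by the residual.
Grids follow the two-grid scheme: a coarse dynamics cube (16³, 18.17 Å)
and a finer spectral cube (32³; 36.34 Å for bulk-scale work, 18.17 Å in
the desk preset whose clusters are small).  The spectral cube floats,
centered on the previous frame's electron centroid snapped to whole
grid spacings; dynamics keeps its cube fixed by default ("initial"),
because re-centering introduces small discontinuous energy jumps that
an NVE ledger would register.

### Quantization filter

`buildKernel(dt, W, T)` samples √w(ν) at the FFT frequencies of a
moving window of W = 150 fs (exposed; 100–200 fs is the sensible range:
long enough to resolve the lowest frequency whose quantum correction
matters, short enough to keep the trajectory margins cheap),
inverse-transforms, centers and renormalizes.  The kernel length is
forced odd so it is exactly symmetric; its transfer gain at the window
frequencies equals √w to 10⁻¹⁰ by construction, verified in tests
together with the w(0)=1 and high-temperature delta limits.  Filtering
acts on the dense 0.5 fs trajectory *before* any frame striding —
striding first would alias the OH stretch — and drops W/2 margins at
each end instead of padding, since padding would fabricate dynamics.
Filtering is not idempotent and is not meant to be: applying it twice
doubles the log-gain, and a regression test guards against an
accidental identity kernel.

### Spectra and statistics

Transitions are binned at 5 meV with optional 10 meV Gaussian smoothing
before sub-band fitting; the smoothing grid is extended by the kernel
half-width so the deposited mass (and hence the spectrum integral ↔
mean Σf identity) is conserved to machine precision.  Moments are
always computed from raw transitions, never from bins.  Each sub-band
is fitted by least squares with a Gaussian (uniform bin weights —
intensity weighting is a defensible alternative, but uniform weighting
keeps the estimator linear and reproducible); FWHM = 2.3548 σ for a
Gaussian line, and the fitted-total maximum and half width are measured
numerically because the total is a mixture.  Confidence intervals for
moments use a seeded nonparametric bootstrap (1000 resamples over
configurations); a closed-form CI recipe would also be possible, but
the bootstrap needs no distributional assumption and its width agrees
with the CLT prediction within 20% on Gaussian test ensembles.  The
classical/quantized comparison uses a one-sided unpaired t test on
per-configuration spectral means, and a one-sided F ratio of f-weighted
spectral variances with Kish effective degrees of freedom (weights make
the nominal df an overcount).  The p-state splitting ⟨E₃−E₁⟩ is
reported per ensemble with t-based CIs, paired across frames when the
ensembles are paired.

### OH bond scaling

`scaleOHBonds` stretches both OH bonds of every molecule by a constant
factor as a uniform scaling about the oxygen followed by a rigid
translation restoring the center of mass.  Uniform scaling preserves
shape, so the HOH angle is unchanged and the principal inertia axes
keep their directions exactly; the transform is exactly invertible.
Whether the angle should co-vary with the bonds is genuinely open; we
hold it fixed because that makes the transform well-defined, invertible
and testable to 10⁻¹⁰.  The ladder (0.90, 0.95, 1.00, 1.05, 1.10)
probes the mechanism behind the quantum broadening: longer OH bonds
stabilize the electron (E₀ decreases) and open the gaps, so the
broadened quantum OH distribution mixes red- and blue-shifted
configurations into a broader band.

## Synthetic generators: what they emulate, what they do not

* `harmonicTrajectory` — deterministic cosines and thermal
  harmonic-oscillator ensembles (exponential energies, uniform phases).
  These are the filter's oracles: the classical→quantum variance map
  has a closed form against which the kernel is validated.  Thermal
  energies are drawn by *stratified* inversion (seeded shuffle), which
  keeps the marginal Boltzmann but pins the ensemble mean at its
  population value to O(1/n²); an oracle ensemble should not fail a 3%
  tolerance by Monte-Carlo accident.
* `toyCluster` — waters on a jittered shell, steepest-descent relaxed
  on the classical force field.  This validates mechanics and plumbing;
  it is *not* a thermally equilibrated structure, and nothing about
  bulk water structure should be inferred from it.
* `toyExcitationTable` — seeded gap ensembles (Normal first gap, fixed
  offsets for higher transitions, configurable oscillator-strength
  rule) for the statistics layer's parameter-recovery tests.

Passing tests on these fixtures demonstrates that the machinery is
correct — transfer gains, sum rules, gradients, estimators — not that
the physical parameter set reproduces any measured spectrum.

## Problem sizes

The package's standard study conditions (the `paper-*` presets) are
200 ps trajectories of n = 45/200 clusters or 1600-water bulk with
spectral solves on 1996 paired configurations — multi-day jobs on one
CPU.  The test suite and the `desk` preset instead use sizes chosen to
exercise every code path at workstation scale: an n = 8 anion for the
1 ps microcanonical conservation check, and an n = 20 anion at 200 K
(0.3 ps thermostatted equilibration, 1.3 ps production, 24 paired
configurations at stride 45 fs, 32³ spectral grid on an 18.17 Å cube,
K = 11, plus a 0.90/1.10 scaling ladder on 8 configurations).  Desk
clusters start cavity-seeded — every water with one OH pointing at the
center, relaxed on the coupled classical+electron surface — because
honestly equilibrated small anions bind the electron in diffuse
surface states, whose spectroscopy is not the interior-state regime
the comparison machinery is aimed at; the seeded cavity (E₀ ≈ −1 eV,
r~g~ ≈ 3 Å at n = 20) emulates interior binding at desk scale.  At
these sizes the qualitative quantum signatures — broader OH
distribution, broader sub-bands, F-test direction, ladder trends — are
reproducible, while printed literature-scale numbers are out of reach
by design.

## Known limitations

* The pseudopotential parameter set is synthetic (see above); absolute
  energies and spectral positions are qualitative.
* No Ewald summation: bulk electrostatics use the tapered cutoff, which
  is part of the method's standard protocol but limits box sizes.
* Desk-scale clusters are small and shallowly bound; surface-state
  ensembles can come close to the continuum edge of the spectral cube,
  where the highest of the K = 11 transitions mix with box states.
* The time-correlation (autocorrelation-function) route to quantized
  spectra is intentionally out of scope; this package implements the
  configuration-filtering route only.
* GSTA is a harmonic-oscillator construction applied mode-by-mode in
  the frequency domain; strongly anharmonic low-barrier motions (e.g.
  proton transfer) are outside its guarantees.
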