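---
title: "MD-PMM excitonic analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MD-PMM excitonic analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonpmm)
```

## The method

The perturbed matrix method (PMM) post-processes a classical MD ensemble of
a pigment–protein complex. Each pigment — the *quantum center* (QC) — is
characterized once, in isolation, by its electronic state energies
$E_i^0$ (Hartree) and the full dipole matrix $\mu_{ij}$ (a.u.; permanent
dipoles on the diagonal, transition dipoles off it), typically from an
excited-state calculation at a QM/MM-optimized geometry. For every frame of
the ensemble, the rest of the system acts on the QC only through its fixed
partial charges: a potential $V$ and an electric field $\mathbf{E}$
evaluated at the QC's instantaneous center of mass. In the unperturbed
eigenbasis the perturbed Hamiltonian, with the multipolar expansion
truncated at the dipole term, is

$$H_{ij} = E_i^0\,\delta_{ij} + q_T V\,\delta_{ij}
          - \mathbf{E}\cdot\boldsymbol{\mu}_{ij},$$

where $q_T$ is the total QC charge. Diagonalizing $H$ per frame gives
perturbed energies and eigenvectors; the **site energy** is
$E_1' - E_0'$ and the **perturbed transition dipole** is
$\boldsymbol{\mu}'_{01} = \mathbf{c}_0^{\mathsf T}\,
\boldsymbol{\mu}\,\mathbf{c}_1$, applied per Cartesian component.

For a set of QCs, per-frame excitonic couplings use the point-dipole
approximation (PDA) between the perturbed transition dipoles placed at the
instantaneous centers of mass,

$$V_{kk'} = \frac{\boldsymbol{\mu}'_k\cdot\boldsymbol{\mu}'_{k'}
  - 3(\boldsymbol{\mu}'_k\cdot\hat n)(\boldsymbol{\mu}'_{k'}\cdot\hat n)}
  {R^3},$$

with $R$ in bohr. The Frenkel excitation matrix $\Delta\tilde H$ — site
energies on the diagonal, couplings off it — is diagonalized per frame; the
squared eigenvector coefficients are the per-pigment contribution weights
of each exciton (each column sums to one). One excitation (the lowest,
Qy-like transition) enters per QC; strongly interacting pigment pairs can
be supplied as a single *dimer* QC whose electronic data were computed for
the pair, which is how short-range effects beyond PDA enter the basis.

### Assumptions and limits

* The environment is a fixed-charge point-charge distribution: no
  polarization, no dielectric screening of the couplings (a scalar
  `screening` factor exists but defaults to 1).
* The QC's electronic data stay frozen at the reference geometry; only its
  center of mass follows the trajectory.
* The perturbation is evaluated at a single point (strict single-center
  multipolar PMM), not atom-distributed.
* Monopole (charged-QC) coupling terms are not implemented; a charged QC in
  the exciton basis raises an error. Charged QCs are fine in the
  site-energy stage, where $q_T V$ only shifts the diagonal.
* Coordinates are assumed pre-imaged (no periodic-boundary handling).

## Units and numerical choices

Internally everything is atomic units (Hartree, bohr, e); Angstrom inputs
are converted on ingest (1 Å = 1.8897259886 bohr) and user-facing outputs
are eV/meV/cm⁻¹/nm (CODATA-2018 constants; `convert_energy()` round-trips
to 1e-12 relative). Other numerical policies:

* **Eigenvector phase**: the largest-magnitude component of every
  eigenvector is made positive, so perturbed-transition-dipole signs are
  reproducible. Degenerate eigenvalues are ordered ascending, then by
  original state index (the LAPACK ordering is stable under this
  convention).
* **Close contacts**: an environment atom within 0.5 Å (configurable) of
  the evaluation point aborts the frame — the point-charge Coulomb
  expression is meaningless there. Frames can be skipped instead
  (`skip_bad_frames`), which is logged.
* **Center of mass**: standard isotope-averaged atomic weights, hydrogens
  included; every atom listed in a QC property file counts (including any
  truncation atoms). `center_of_mass()` accepts per-frame coordinates so
  the trajectory geometry, not the reference geometry, sets the evaluation
  point.
* **Degenerate site energies** (gap exactly 0) are allowed and flagged
  with a warning rather than treated as errors.
* **Histogram binning** defaults to Freedman–Diaconis; a fixed bin width
  in meV may be requested instead.
* **Electrochromic shifts** are rounded to integer meV, matching how such
  tables are conventionally printed.

## The synthetic world

`synthetic_spec()` states a chlorophyll-like world once; it is the ground
truth the test suite measures against, not a tuning knob:

* first excitation gaps spread over **1.87–1.97 eV**, second excitations
  **0.4 eV** higher — the Qy/Qx scale of chlorophyll *a* in a protein;
* transition dipoles of **2.0 a.u.**, giving oscillator strengths ≈ 0.2 at
  1.9 eV, the observed Qy scale;
* permanent-dipole differences of ~1.5 a.u. between ground and excited
  states — the lever arm that turns field fluctuations into site-energy
  fluctuations;
* **150** environment point charges with zero-mean fixed charges
  (sd 0.15 e), placed at least **6 Å** from every QC center of mass and
  jittered per frame by an isotropic **0.3 Å** Gaussian; QCs undergo
  0.05 Å rigid-body jitter so centers of mass (and hence couplings) move;
* frames **10 ps** apart, seed mandatory (R's Mersenne–Twister).

The 6 Å exclusion and 0.15 e charge spread were calibrated — against the
independent brute-force reference, before the acceptance tests were
written — so that site-energy distributions are roughly Gaussian
(|skewness| < 0.5) with standard deviations in the 0.005–0.026 eV band
observed for antenna chlorophylls. A charge allowed closer than ~4 Å sits
in the strongly nonlinear Coulomb regime and produces skewed, fat-tailed
distributions that no longer resemble protein electrostatics.

The optional **two-basin switch** relocates a small charged group
(default: 6 charges of +0.35 e) between two sites 4 Å apart in alternating
blocks of frames. This emulates a slow conformational two-state process and
produces a bimodal first-exciton distribution; the two basin reference
energies are computable exactly (unjittered configurations) via
`reference_frame_quantities()`.

What the generator does **not** emulate: real protein geometry and charge
topology, correlated (non-isotropic) motions, vibronic structure, and
polarization response. A green test therefore establishes that the
*machinery* — Coulomb sums, Hamiltonian assembly, diagonalization,
couplings, statistics — is correct and internally consistent, not that any
particular protein's numbers are reproduced. Static electrochromic offsets
in the synthetic world (set by each seed's frozen charge placement) can
exceed the tens-of-meV range typical of real antenna proteins; only the
fluctuation widths were calibrated.

## Validation design

Two fully independent code paths exist. The pipeline uses vectorized sums
and LAPACK (`eigen`); the reference (`oracle_frame()`, `jacobi_eigen()`)
uses plain element-wise loops and cyclic Jacobi rotations, and calls none
of the pipeline's functions. `ground_truth_check()` compares the two frame
by frame; agreement to 1e-10 Hartree on site energies, couplings and
exciton energies is an acceptance criterion (observed: ~1e-16). Closed
forms (2×2 eigenvalues $\sqrt{\Delta^2+4V^2}$, PDA orientation factors
$\kappa = 1, -2, 0$, $1/R^3$ scaling), per-frame trace conservation
($\sum_a E_a^{exc} = \sum_k E_k^{site}$ to 1e-9 eV), doubly stochastic
contribution matrices (1e-10), and statistical recovery at $n = 3000$
(sample means within $3\sigma/\sqrt{n}$ of the unjittered reference;
mixture means of the two-basin world within 3 SE of the basin references)
complete the acceptance suite.

## The absorption line shape

The exact line-shape recipe of the upstream methodology lives in
supplementary material that is not part of this package's contract, so a
documented stand-in is implemented: each exciton of each frame contributes
a Gaussian kernel on the wavelength axis at $\lambda = hc/E_a$, weighted by
its dipole strength $|\boldsymbol{\mu}_{exc}|^2$ (coefficient-weighted sum
of the sites' perturbed transition dipoles), and the sum is normalized to
unit area. The kernel width (nm) is an explicit user parameter — it stands
in for homogeneous broadening and is *not* derived from the dynamics; the
ensemble spread supplies the inhomogeneous part. Reported metrics: the
global peak, the FWHM bandwidth, and the splitting to the most prominent
secondary peak *or shoulder*. Shoulders are located via second-derivative
sign structure: a single smooth band has exactly two first-derivative
extrema, so any additional extremum pair marks a merged sub-band. This
reproduces the qualitative shoulder/splitting observables of
room-temperature antenna spectra without claiming the upstream recipe.

## Open design decisions, resolved

* **Subpopulations** are operationalized as a two-component 1-D Gaussian
  mixture fitted by EM with deterministic quantile initialization (no
  mixture package is required at runtime). A degenerate fit (vanishing
  weight or variance) falls back to a unimodal summary with a warning.
* **Per-frame vs fixed geometry in couplings**: couplings use per-frame
  centers of mass and per-frame perturbed dipoles; a static mode is
  available by assembling `build_excitation_matrix()` directly from
  tabulated values.
* **Dimers** are never synthesized from two monomer property files; a
  dimer QC must come from a pair calculation. Combining monomer data would
  silently drop the short-range interactions that motivate a dimer basis
  in the first place.
* **Config format**: the CLI reads JSON configs (a YAML subset) since no
  YAML parser is guaranteed in the target environment; the interface is
  unchanged.
* **Time windows**: `subsample_frames()` is half-open at the start
  ($t \in (t_0, t_1]$ at stride $s$), so a 30 ns window at 10 ps stride
  selects exactly 3000 frames — the convention that matches "the final
  30 ns saved every 10 ps" bookkeeping.

## Known limitations

PDA degrades for closely spaced pigments (center separations comparable to
the dipole extent); the dimer-basis mechanism is the intended workaround.
No transition-charge (TrESP) couplings, no polarizable embedding, no
energy-transfer kinetics, and no fitting to experimental spectra are
provided. The brute-force reference is intentionally slow (plain R loops)
and meant for validation at small scale, not production use.
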