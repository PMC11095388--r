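# excitonpmm

Perturbed-matrix-method (MD-PMM) excitonic analysis of pigment–protein
complexes in R.

## The problem

The optical properties of photosynthetic antenna proteins — which pigment
absorbs where, how excitations delocalize, where the low-energy "trap"
states sit — are set by two ingredients: the **site energy** of each
pigment (its lowest Qy excitation energy inside the protein) and the
**excitonic couplings** between pigments. Neither is measurable pigment by
pigment; both fluctuate with protein conformation. A practical route is to
run classical molecular dynamics of the whole complex, compute each
pigment's electronic structure once in the gas phase, and then, for every
MD frame, treat the instantaneous environment as an electrostatic
perturbation of that fixed electronic Hamiltonian. That is the perturbed
matrix method. This package implements the full post-processing pipeline
for users who already have (a) per-pigment excited-state data (energies and
the dipole matrix) and (b) an ensemble of environment configurations with
fixed partial charges — or who want to validate the machinery on synthetic
data with a known ground truth.

## The model

Each pigment ("quantum center", QC) carries gas-phase state energies
`E_i⁰` and a dipole matrix `μ_ij` (permanent dipoles on the diagonal,
transition dipoles off it), all in atomic units. For every frame, the
environment's point charges produce a potential `V` and field `E` at the
QC's instantaneous center of mass, and the perturbed Hamiltonian in the
unperturbed eigenbasis is

    H_ij = E_i⁰ δ_ij + q_T V δ_ij − E · μ_ij

(`q_T` = total QC charge; the multipolar expansion is truncated at the
dipole term). Diagonalization gives perturbed energies — the site energy is
`E₁′ − E₀′` — and perturbed transition dipoles `μ′₀₁ = c₀ᵀ μ c₁`. Couplings
between QCs `k, k′` use the point-dipole approximation at the centers of
mass,

    V_kk′ = [ μ′_k · μ′_k′ − 3 (μ′_k · n̂)(μ′_k′ · n̂) ] / R³ ,

and the per-frame Frenkel excitation matrix (site energies on the diagonal,
couplings off it) is diagonalized into exciton energies, eigenvectors and
per-pigment contribution weights (squared coefficients). Ensemble
statistics, two-subpopulation (Gaussian-mixture) analysis of the first
exciton, and a dipole-strength-weighted Gaussian-kernel absorption line
shape complete the pipeline.

## Worked example

```r
library(excitonpmm)

# a synthetic world with known ground truth: 3 chlorophyll-like QCs,
# 500 frames of a jittering charge environment
spec <- synthetic_spec(n_qcs = 3, n_frames = 500, seed = 42)
ds <- generate_dataset(spec, "demo")

traces <- run_site_energy_stage(ds$ensemble, ds$qcs)
site_energy_statistics(traces)[, c("qc", "n", "mean_eV", "sd_eV", "skewness")]
#>    qc   n mean_eV   sd_eV skewness
#> 1 Q01 500   1.852 0.00607  0.00588
#> 2 Q02 500   2.065 0.00979  0.26040
#> 3 Q03 500   2.061 0.00794 -0.12962

sols <- run_exciton_stage(traces, ds$ensemble, ds$qcs)
round(coupling_statistics(sols)$mean, 2)   # cm^-1
#>       Q01    Q02    Q03
#> Q01  0.00  48.83   2.20
#> Q02 48.83   0.00 -22.39
#> Q03  2.20 -22.39   0.00

fd <- first_exciton_distribution(sols, fit_mixture = FALSE)
sprintf("first exciton: %.4f +/- %.4f eV", mean(fd$energies), sd(fd$energies))
#> "first exciton: 1.8515 +/- 0.0061 eV"

sp <- absorption_lineshape(sols, width = 3, grid = seq(550, 720, by = 0.05))
sprintf("peak %.1f nm, FWHM %.1f nm", sp$peak_nm, sp$bandwidth_nm)
#> "peak 601.4 nm, FWHM 75.4 nm"
```

The per-QC means sit at the built-in gaps plus each configuration's static
electrochromic shift; the meV-scale standard deviations come from the
positional jitter of the environment charges. Every number above is
reproducible bit-for-bit under the same seed, and
`ground_truth_check(ds$qcs, ds$ensemble, traces, sols)` re-derives all of
it with an independently coded brute-force reference (plain Coulomb loops
plus a Jacobi eigensolver), agreeing to ~1e-16 Hartree per frame.

Tabulated site-energy/coupling tables (13-pigment antenna layout) can be
summarized without any trajectory:

```r
st <- read_site_table(system.file("extdata", "cp43_site_energies.csv",
                                  package = "excitonpmm"))
electrochromic_shift(st)      # integer meV vs gas phase
range_summary(st$E_monomer, st$site)
```

## Command line

```sh
Rscript -e 'excitonpmm::excitonpmm_cli()' simulate --config sim.json --seed 5 --out data/
Rscript -e 'excitonpmm::excitonpmm_cli()' excitons --config run.json --out out/
Rscript -e 'excitonpmm::excitonpmm_cli()' summarize-tables site.csv couplings.csv
```

Subcommands: `simulate`, `site-energies`, `excitons`, `spectrum`,
`summarize-tables`; flags `--config`, `--seed`, `--out`,
`--skip-bad-frames`, `--log-level`. Configs are JSON; every run emits a
`run_log.json` with the config hash and seed. Exit codes: 0 ok, 1 data
error, 2 usage error.

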