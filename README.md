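# alchemfe

Alchemical free-energy calculations for many-body potentials: softcore
dimer-curve construction, λ-scaled decoupling of two-body features,
Hamiltonian replica exchange, and TI/BAR/MBAR estimation — a desk-scale R
toolkit validated against analytic and brute-force oracles.

## The problem

Solvation free energies (and, from the water/octanol pair of legs, log P)
are computed alchemically: a coupling parameter λ interpolates a Hamiltonian

    H(r, λ) = λ H₁(r) + (1 − λ) H₀(r)

between the fully interacting (λ = 1) and decoupled (λ = 0) end states, and
the free-energy difference is recovered from samples of the intermediate
windows, e.g. by thermodynamic integration

    ΔG = ∫₀¹ ⟨∂H/∂λ⟩_λ dλ

or by the multistate Bennett acceptance ratio (MBAR), which pools all
windows optimally. Potentials that model the full repulsive wall diverge
when partially decoupled atoms overlap, so two softening devices are
needed — and are the core of this package:

* **Softcore short-range curves.** Below an automatically selected
  switching point r_s on the repulsive wall, the radial pair force is
  replaced by the polynomial `a·r¹⁰ + b`, matched in value and gradient to
  the reference force at r_s; the softened energy is its analytic integral,
  C¹ at the seam and finite at r = 0. The switching point is the largest
  separation at which |dF/dr| still reaches a floor (default 3 eV/Å²), so
  the position and curvature of the energy minimum are untouched. The
  Beutler softcore Lennard-Jones form
  `U = 4ελⁿ[(α(1−λ)^m + (r/σ)⁶)⁻² − (α(1−λ)^m + (r/σ)⁶)⁻¹]` is also
  provided (α = 0.5, n = 4, m = 2 by default).

* **λ-scaled two-body features.** In a body-ordered graph potential, every
  edge feature crossing the solute/solvent boundary is scaled by
  α_ij = λ (α_ij = 1 otherwise). At λ = 0 the interaction graph equals that
  of the separated components, so the decoupled energy splits exactly into
  solute + solvent; at λ = 1 the scaling vanishes from the expression.

Around these sit a BAOAB Langevin integrator, a Monte Carlo barostat,
L-BFGS minimisation, replica exchange over a λ schedule with transition
diagnostics, automated equilibration detection and decorrelation, MBAR/BAR/
TI estimators with asymptotic uncertainties, and an end-to-end solvation /
log P pipeline. A synthetic module generates every test input (analytic
dimers, harmonic λ families, Gaussian work samples, small Lennard-Jones
fluids) with closed-form answers, so the whole stack is verifiable offline.

## Worked example

Soften a Lennard-Jones dimer curve, then run a full alchemical leg on the
3-D tethered harmonic fixture, whose exact answer is
ΔG = (3/2) k_BT ln(k₁/k₀):

```r
library(alchemfe)

curve <- analytic_dimer("lj", params = list(epsilon = 1, sigma = 1))
rs   <- select_switch_point(curve, gradient_floor = 200)  # reduced units
spec <- fit_force_polynomial(curve, rs, gradient_floor = 200)
print(spec)
#> softcore_spec LJ-LJ: r_switch = 1.0504 A, a = -12.8439, b = 29.32, E(0) = 28.03 kcal/mol

cfg <- run_config(
  system  = list(kind = "single_particle"),
  model   = list(kind = "harmonic", k0 = 1, k1 = 4),
  n_windows = 5,
  state   = list(temperature = 1, pressure = NULL, kB = 1),
  sampler = list(dt = 0.05, friction = 1, steps_per_iteration = 25,
                 n_iterations = 150, equilibration_steps = 300,
                 minimize = FALSE),
  seed = 42)
report <- run_solvation_leg(cfg)
print(report)
#> solvation_report: dG = 2.0709 +/- 0.0596 (5 windows)
cat(sprintf("exact (3/2) ln(4) = %.4f\n", 1.5 * log(4)))
#> exact (3/2) ln(4) = 2.0794
```

The report's `dG` is the coupling free energy G(λ = 1) − G(λ = 0) in model
energy units (reduced units here, since kB = 1); `dG_err` is the asymptotic
MBAR standard error on decorrelated samples, and the estimate agrees with
the Gaussian closed form well within it. `report$transition_matrix` shows
the replica mixing between λ windows (rows sum to 1; a healthy schedule is
at least tridiagonally connected):

```r
round(report$transition_matrix, 2)
#>      [,1] [,2] [,3] [,4] [,5]
#> [1,] 0.59 0.25 0.14 0.01 0.00
#> [2,] 0.25 0.36 0.25 0.13 0.01
#> [3,] 0.13 0.22 0.22 0.31 0.11
#> [4,] 0.03 0.15 0.28 0.31 0.24
#> [5,] 0.00 0.02 0.11 0.23 0.64
```

When an output directory is configured, the reduced-potential matrix is
archived as delimited text with a JSON sidecar, and
`estimate_from_ukn(dir)` reproduces the reported ΔG bit-for-bit.

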