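---
title: "Alchemical free energies with softcore many-body potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical free energies with softcore many-body potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemfe)
```

## The problem

Solvation free energies — the reversible work of transferring a molecule
from vacuum into a solvent — are among the most useful quantities molecular
simulation can deliver, both as force-field benchmarks and, through the
octanol/water pair of legs, as the route to log P. The standard machinery
is *alchemical*: because free energy is a state function, the physical
transfer can be replaced by a nonphysical path in which the solute–solvent
interactions are switched off by a coupling parameter λ,

$$H(\mathbf r, \lambda) = \lambda H_1(\mathbf r) + (1-\lambda) H_0(\mathbf r),$$

and the free-energy difference recovered by estimators such as
thermodynamic integration,

$$\Delta G = \int_0^1 \left\langle \frac{\partial H}{\partial \lambda}
\right\rangle_\lambda \, d\lambda,$$

or, preferably, the multistate Bennett acceptance ratio (MBAR), which
pools samples from every λ window in a statistically optimal way.

Two ingredients make this work with *many-body* (machine-learned style)
potentials, and those two ingredients are what this package implements:

1. **Softcore short-range curves.** Partially decoupled atoms can overlap;
   a potential fitted to repulsive quantum-mechanical walls then diverges.
   We soften each pairwise dimer curve below a switching point
   $r_s$ by replacing the radial force with the polynomial $a r^{10} + b$,
   matched in value and first derivative to the reference force at $r_s$,
   and obtain the softened energy by analytic integration of that
   polynomial. The energy is then $C^1$ at the seam and finite down to
   $r = 0$, while the curve at $r \ge r_s$ — the region that controls
   equilibrium properties — is bit-identical to the reference.

2. **λ-scaled two-body features.** In a body-ordered potential the site
   energy is a nonlinear function of pooled two-body features. We scale
   each feature by a per-edge factor
   $\alpha_{ij} = \lambda$ if exactly one of $i, j$ belongs to the solute,
   and $\alpha_{ij} = 1$ otherwise. At $\lambda = 1$ the factors vanish from
   the expression; at $\lambda = 0$ the interaction graph is exactly that of
   the separated components, so the decoupled energy splits into
   solute-alone plus solvent-alone — the end-state consistency on which a
   free-energy cycle depends. Because the scaling acts on the one-particle
   basis, it produces genuinely λ-dependent many-body interactions, which
   keeps neighbouring windows overlapping on a near-linear λ schedule.

## The switching-point rule

The switching point trades two failure modes against each other: too close
to the minimum and the softening perturbs equilibrium curvature; too far up
the wall and the capped energies become enormous and hard to learn. We
therefore choose the *largest* separation on the repulsive wall (strictly
below the energy minimum) at which the magnitude of the force gradient
still reaches a floor, by default 3 eV/Å² (69.18 kcal/mol/Å² in the
package's kcal/mol–Å working units). The floor minimises the gradient at
the seam subject to never touching the minimum, and in practice caps pair
energies a few hundred kcal/mol above the well. The search direction and
discretisation are not uniquely pinned down by that verbal rule; we resolve
it as a bisection (tolerance $10^{-6}$ Å) for the outermost root of
$|dF/dr| = \text{floor}$ on the wall, which is deterministic and
grid-independent. When a curve's wall never reaches the floor the curve is
reported as unsoftenable rather than silently softened.

Reference force derivatives use analytic callables when the dimer curve
carries them (all synthetic curves do) and 4th-order central differences on
the grid otherwise, so tabulated input is first-class.

For pair interactions of Lennard-Jones form the package also provides the
classical Beutler softcore
$$U(\lambda, r) = 4\epsilon\lambda^n\!\left[\bigl(\alpha_{LJ}(1-\lambda)^m +
(r/\sigma)^6\bigr)^{-2} - \bigl(\alpha_{LJ}(1-\lambda)^m +
(r/\sigma)^6\bigr)^{-1}\right]$$
with the original constants $\alpha_{LJ} = 0.5$, $n = 4$, $m = 2$ as
defaults; it reduces exactly to Lennard-Jones at $\lambda = 1$, vanishes at
$\lambda = 0$, and equals $14\epsilon$ at full overlap for
$\lambda = 1/2$ — a useful hand-checkable value.

## The model zoo

The λ-scaling mechanism is implemented in a miniature invariant
body-ordered model (`body_ordered_model()`): Gaussian radial basis ×
smooth cosine cutoff × species embedding per edge, pooled per atom, with
polynomial readouts up to body order 3 and an optional second
message-passing layer (the α factors are applied identically at every
layer, since the one-particle basis is rebuilt per layer). We deliberately
stay in the invariant (l = 0) limit: the property under test — scaled
two-body features entering *nonlinear* many-body readouts — does not
require equivariant tensor algebra, and the mechanism applies to any
architecture that builds site energies from two-body terms. Model weights
are random under a recorded seed, not trained; every property we assert
(end-state consistency, λ-smoothness, invariances) is weight-independent.

Alongside it live the fixtures with known answers: an alchemical
Lennard-Jones fluid (solvent–solvent plain truncated-shifted LJ,
solute–solvent Beutler softcore), a tethered harmonic particle whose leg
free energy is $(d/2)\,k_BT \ln(k_1/k_0)$, and an ideal gas. All synthetic
fluids use reduced units ($\epsilon = \sigma = k_B = 1$); the thermodynamic
state object carries $k_B$ and the pressure–volume conversion explicitly,
so the same samplers and estimators serve both reduced-unit fixtures and
kcal/mol systems.

## Sampling

Dynamics is BAOAB-split Langevin (chosen for its configurational accuracy
at fs-scale steps), with protocol defaults mirroring the standard
condensed-phase recipe: 1 fs-scale time step, 1 ps⁻¹-scale friction,
Monte Carlo barostat at 1 atm for NPT legs, energy minimisation (L-BFGS)
and NPT equilibration before production, 16 λ windows with swap attempts
every 1000 steps. Every constant is configurable; the shipped tests and
the acceptance script scale the problem down (tens of particles, tens of
steps per exchange iteration, hundreds of iterations) so the full pipeline
runs on one CPU in minutes — these sizes are a deliberate design point of
the desk-scale fixtures, whose oracles remain exact at any size.

Replica exchange swaps *thermodynamic states* (λ values), not coordinates
— cheaper and statistically identical. Each sweep makes several randomly
chosen adjacent-window attempts, accepted with the Metropolis probability
$\min(1, e^{-\Delta})$,
$\Delta = [u^*_i(x_j) + u^*_j(x_i)] - [u^*_i(x_i) + u^*_j(x_j)]$ in
reduced potentials ($u^* = u/k_BT$, plus $pV/k_BT$ in NPT). Many attempts
per sweep approximate all-pair mixing while each individual attempt remains
a neighbour swap; this reconciles the two natural readings of
"exchange between adjacent windows" versus "exchanges between all
replicas", and the empirical transition-probability matrix (the standard
mixing diagnostic) is exposed so the choice can be audited — a healthy
schedule is at least tridiagonally connected.

Randomness is organised as one private Mersenne-Twister stream per replica
plus one for the swap scheduler, all fanned out deterministically from a
master seed, so runs reproduce bit-for-bit regardless of scheduling order.

The default λ schedule places about half of the 16 windows inside
$[0.15, 0.4]$, where the curvature of $\partial H/\partial\lambda$ is
greatest for decoupling transformations, with exact endpoints at 0 and 1.

## Estimation

Per-window time series are first truncated by automated equilibration
detection — scan candidate truncation points $t_0$, compute the
statistical inefficiency $g = 1 + 2\sum_t C(t)(1 - t/T)$ (autocorrelation
truncated at its first non-positive value; FFT-based, biased $1/T$
normalisation) on the remainder, keep the $t_0$ maximising
$N_\text{eff} = (T - t_0)/g$ — then subsampled with stride $g$. The scan
uses every candidate point for short series and a strided grid (capped at
1000 points) beyond, which bounds cost without moving the optimum
materially.

MBAR is solved by self-consistent iteration followed by a Newton polish
(gauge $f_1 = 0$; convergence when the self-consistency residual
$|\sum_n W_{nk} - 1|$ drops below $10^{-12}$, with a fall-back to the
self-consistent update whenever a Newton step fails to improve that
residual). Uncertainties come from the standard asymptotic covariance in
its SVD form; unsampled ($N_k = 0$) states are handled perturbatively.
BAR is implemented independently as the root of the Bennett equation
(bracketed `uniroot`, tolerance $10^{-10}$), which gives the K = 2
cross-check MBAR must reproduce to $10^{-8}$. TI uses trapezoidal
quadrature — the λ schedules here are dense enough that a fancier rule
would only obscure the error budget — with window errors propagated as
independent.

The NPT reduced potential includes the $pV$ term; omitting it is the
classic way to corrupt barostatted free energies.

Uncertainty of the final ΔG is the asymptotic MBAR covariance evaluated on
the decorrelated samples; correlations between windows induced by replica
exchange are neglected, which is the usual practice and conservative once
decorrelation has been applied per window.

## What the synthetic generators do and do not show

The generators produce analytic dimer curves (Lennard-Jones, Morse),
harmonic λ families with exact Gaussian partition functions,
Crooks-consistent Gaussian work samples (forward $N(\mu, \sigma^2)$ implies
reverse $-N(\mu-\sigma^2, \sigma^2)$ and $\Delta f = \mu - \sigma^2/2$),
and small Lennard-Jones fluids whose decoupling free energy is checked
against an independent Widom test-particle insertion estimate
($\mu_\text{ex} = -k_BT \ln\langle e^{-\beta\Delta u}\rangle$). They target
*statistical* realism — correlated time series, finite overlap between
windows, genuine sampling noise — not chemical realism: there is no
molecular structure, no electrostatics, no water or octanol. Passing tests
therefore demonstrate that the machinery (softening, λ-coupling, sampling,
decorrelation, estimation) is correct, not that any particular chemical
prediction is accurate; chemical accuracy is a property of the potential
the machinery is wrapped around.

## Numerical choices and degenerate inputs

* Working units kcal/mol and Å, with the 3 eV/Å² floor converted via
  1 eV = 23.0605 kcal/mol; reduced units in the synthetic fluids via the
  explicit $k_B$ field.
* Cubic periodic boxes with minimum-image convention, enforced by
  requiring the box side to be at least twice the model cutoff (a box
  builder raises and logs the side when a density or padding request
  violates it). Rhombic-dodecahedral solvent economy is irrelevant at toy
  scale.
* The L-BFGS line search is protected against steep repulsive walls by
  clipping the gradient norm and capping the energy it sees; convergence
  is judged on true forces. Without this the Wolfe interpolation can stall
  on a wall where the trial step lands at $10^{14}$ energy units.
* Zero-variance series return $g = 1$ with a degeneracy flag;
  equilibration-detection ties break towards discarding less data.
* A barostat volume proposal of zero is accepted unconditionally; the
  proposal width auto-tunes towards a healthy acceptance fraction.
* Serialised curves and u_kn matrices are written at 17 significant
  digits, so re-estimation from an archive reproduces reported free
  energies bit-for-bit.
* The energy-cap diagnostic ("how far above the minimum does the softened
  curve top out") is reported, never enforced: it is an emergent property
  of the gradient-floor rule.

## Known limitations

No long-range electrostatics, no equivariant feature channels, no
nonequilibrium work estimators, no training loop: the package implements
the alchemical machinery around a potential, not the potential itself.
Free energies on the shipped fixtures carry the statistical error of
desk-scale sampling; the acceptance checks are therefore phrased against
each estimate's own uncertainty rather than against fixed literature
values.
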