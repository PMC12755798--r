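---
title: "Structured plus random interactions in generalized Lotka-Volterra communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured plus random interactions in generalized Lotka-Volterra communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structglv)
```

## The model and its assumptions

The package studies communities of $S$ species with rescaled abundances
$x_i(t)$ obeying

$$\frac{dx_i}{dt} = x_i\Big[\,1 - x_i + \sum_j A_{ij}\,x_j\,\Big] + m ,$$

a generalized Lotka-Volterra system in which every species has unit
carrying capacity and self-regulation, all heterogeneity sits in the
interaction matrix, and a small immigration rate $m$ (default $10^{-8}$)
keeps losing species at a positive floor from which they can re-invade.
Demographic and environmental noise are deliberately absent: all
stochasticity is *quenched* in the interactions.

The interaction matrix superposes two components,
$A_{ij} = \mu_{ij} + \sigma z_{ij}/\sqrt{S}$:

* a **structural matrix** $\mu_{ij} = S^{-1}\sum_\lambda
  \mathcal{S}_i(\lambda)\,\mathcal{I}_j(\lambda)$ built from impact traits
  $\mathcal{I}_i(\lambda)$ (per-capita contribution of species $i$ to
  collective function $\lambda$) and sensitivity traits
  $\mathcal{S}_i(\lambda)$ (effect of that function on the growth of
  species $i$). Functions are species-averaged linear combinations
  $f_\lambda = S^{-1}\sum_i \mathcal{I}_i(\lambda) x_i$ — group biomasses,
  public-good levels, clade biomasses. Because there are few functions
  ($n_F \ll S$), $\mu$ is low-rank; conversely any low-rank matrix can be
  split into traits by singular value decomposition
  (`decompose_structure()`), which is also how the package recovers traits
  from a given matrix.
* a **random matrix** of i.i.d. entries $z_{ij}$ with zero mean and unit
  variance (Gaussian by default; a bounded uniform variant exists because
  the macroscopic theory only uses the variance). The $1/\sqrt S$ scaling
  keeps single random interactions small relative to the aggregate. The
  diagonal of $z$ is zeroed: self-regulation is already the $-x_i$ term,
  and $O(\sigma/\sqrt S)$ diagonal noise would be a silent change of model.

Nonlinear functional responses, correlated disorder ($A_{ij}$–$A_{ji}$
correlations), sparse randomness and non-identical disorder variances are
out of scope.

## Structure archetypes

`group_structure()` builds non-overlapping functional groups (impact =
membership indicator, sensitivity = rows of a group-coupling matrix);
`trait_structure()` wraps arbitrary trait tables (public goods / resource
mediation); `tree_structure()` places species at the leaves of a balanced
binary tree with one function per subtree and one sensitivity coefficient
per level, producing the nested block-constant (fractal) matrices typical
of phylogenetically structured interactions; `power_law_structure()` uses a
single function (total abundance) with heavy-tailed sensitivities;
`many_groups_structure()` samples many groups with strong, heterogeneous,
purely competitive couplings.

Two builder choices deserve a note:

* **Tree function set.** Every internal node at every level is a function,
  so $n_F = S - 1$: trees are *not* low-rank relative to $S$, and the
  general constructor therefore enforces only $n_F \le S$ while warning
  (suppressible) when $n_F > S/10$. The decomposition gate
  (`decompose_structure()` refusing retained rank $\ge S/2$) is kept
  strict, so trees are intentionally rejected there.
* **Many-groups sampler.** The couplings are drawn as
  $b_{\lambda\mu} = -n_F\,u_{\lambda\mu}$, $u \sim
  \mathrm{Uniform}(\bar a(1-s), \bar a(1+s))$, i.e. on the scale of group
  mean abundances the group-level Lotka-Volterra system has competition
  coefficients of mean $\bar a$ (default 1, comparable to
  self-regulation). Strong spread plus weak immigration makes many
  realizations cycle or turn over chaotically between a few dominant and
  many rare groups, while boundedness is guaranteed because the couplings
  are competitive; mean-zero strong couplings were rejected because their
  mutualistic tail causes finite-time runaway growth at moderate sizes.
  Realizations differ qualitatively, which is intrinsic to the setting:
  the showcase community is a realization (seed 3) *chosen* for persistent
  group-level oscillations, exactly as one chooses a group matrix to
  generate complex dynamics.

## Simulation choices

`integrate_glv()` works in linear abundance space (log space is broken by
the additive $+m$) with `deSolve`. The default method is the non-stiff
Adams multistep: despite abundances spanning eight decades the dynamics is
not stiff — every per-capita rate is $O(1)$, including for species at the
immigration floor — and avoiding Jacobian factorizations makes $S = 2000$
runs about twenty-five times faster than lsoda, with identical
trajectories at the same tolerances; lsoda remains the automatic fallback.
Defaults `rel_tol = 1e-8`, `abs_tol = 1e-12` (< $m$); the right-hand side
is left unclamped because non-smooth clamping at zero destroys the
integrator's step-size control, and with $m > 0$ the flow is repelled from
zero anyway. A run whose right-hand side max-norm falls below
`equilibrium_tol` ($10^{-9}$) is declared at a fixed point and can stop
early; a run whose abundance exceeds `x_cap` ($10^4$) is aborted as
runaway growth — a genuine dynamical regime of mean-zero disorder past the
bulk transition at these sizes, not an integrator artifact.

Initial abundances default to $\mathrm{Uniform}(0.1, 1)$ draws, seeded.
Species with stationary mean abundance below `extinction_factor`$\times m$
(default $10\,m$) are censused as extinct; any factor in $10$–$10^4$
gives the same census when survivors are $O(1)$ abundant, and this
insensitivity is itself a shipped test.

Trajectory diagnostics follow the displays used for multiscale dynamics:
`hilbert_embedding()` (FFT analytic signal) projects an oscillation onto a
loop in the complex plane so species can be compared with their group
mean; `fluctuation_variances()` compares the mean temporal variance of
species abundances with that of group magnitudes rescaled by
$(S/s_\lambda)^2$, so that perfect within-group synchrony gives equal
values and asynchronous species noise averages out at the group level.

## Equilibrium theory

At a stable equilibrium the macroscopic state is the function vector
$f^\star$ plus one disorder degree of freedom, the heterogeneity
$\gamma = \sigma\sqrt{C^\star}$ with $C^\star$ the equal-time correlator.
With modal abundances $x_i^+ = 1 + \sum_\lambda \mathcal{S}_i(\lambda)
f_\lambda^\star$, the closed system is

$$f_\lambda^\star = \frac{\gamma}{S}\sum_i \mathcal{I}_i(\lambda)\,
  \omega_1\!\big(x_i^+/\gamma\big), \qquad
  1 = \frac{\sigma^2}{S}\sum_i \omega_2\!\big(x_i^+/\gamma\big),$$

where $\omega_k(w)$ is the $k$-th moment of a unit Gaussian truncated at
$-w$. The closed forms $\omega_0 = \Phi$, $\omega_1 = w\Phi + \psi$,
$\omega_2 = (1+w^2)\Phi + w\psi$ are verified against adaptive quadrature
in the test suite and guarded by a Mills-ratio expansion for $w < -8$
where the naive forms cancel catastrophically. Equilibrium abundances are
truncated Gaussians $x_i^\star = \max(0, x_i^+ + \gamma\xi_i)$, the
diversity is $\phi^\star = \overline{\omega_0(x_i^+/\gamma)}$, and the
species abundance distribution is
$\rho(x) = (1-\phi^\star)\,\delta(x) + \Theta(x)\,(S\gamma)^{-1}\sum_i
\psi((x - x_i^+)/\gamma)$. The $1/S$ in the continuous part is our
normalization choice — the mixture is read as a species average so that
$\rho$ integrates to one, consistent with the diversity being a species
average.

### Solver

* $\sigma = 0$ (`solve_sigma_zero()`): the system
  $f_\lambda = S^{-1}\sum_i \mathcal{I}_i(\lambda)\max(0, x_i^+)$ is
  piecewise linear; we use *support iteration* (guess the surviving set,
  solve the linear system, recompute the set), falling back to damped
  fixed-point iteration (damping 0.3) when the support cycles. Starting
  from $f = 0$ (all species extant) is the default; competitive-exclusion
  systems are multistable and the returned branch follows `init`.
  `sigma_zero_equilibria()` enumerates all feasible supports for
  group-built communities with few groups, including dynamically unstable
  interior points.
* $\sigma > 0$ (`solve_self_consistency()`): damped fixed-point iteration
  on $f$ (damping 0.5) with a nested bracketed 1-D root solve for
  $\gamma$ at every step (the bracket is found on a log-spaced scan;
  with several roots the one nearest the previous $\gamma$ is taken, which
  keeps continuation on its branch). When a starting point is supplied the
  solver first tries a damped Newton iteration on $(f, \log\gamma)$ with a
  finite-difference Jacobian: along a continuation path Newton tracks
  branches through regions where the fixed-point map is unstable. Newton
  is also the fallback when the damped iteration stalls. Tolerance
  $10^{-9}$ on the residual of the closed relations.

Branches matter. The two-group showcase has an asymmetric
(exclusion-continued) branch that terminates in a fold near
$\sigma \approx 1.1$, beyond which only a branch with equal modal
abundances in both groups survives; the solver follows the continued
branch and lands on the surviving one past the fold. For strongly
structured communities (many-groups) the equilibrium branch may not exist
at small $\sigma$ at all — the community is then genuinely
out-of-equilibrium — so `sigma_scan()` continues *downward* from large
$\sigma$ by default and retries failed grid points from their neighbours.

## Stability

Two separate routes destabilize the equilibrium:

* **Bulk** (randomness-driven): $\phi^\star\sigma^2 - 1 > 0$
  (`bulk_index()`). For a structureless community the equilibrium branch
  terminates exactly at the criterion ($\sigma_c = \sqrt 2$,
  $\phi^\star = 1/2$), which `bulk_critical_sigma()` exploits by treating
  solver failure as a positive indicator during bisection.
* **Collective** (structure-driven): outlier eigenvalues of the
  pseudo-Jacobian $\mathcal{J} = -\mathrm{diag}(x^\star)(I - \mu)$
  crossing the imaginary axis, typically as a complex (Hopf) pair
  (`outlier_spectrum()`, `classify_regime()`).

The diagonal abundances in $\mathcal{J}$ admit two conventions, both
exposed. The `"mean"` convention uses the disorder-averaged abundances
$\gamma\,\omega_1(x_i^+/\gamma)$; on group-built structures these are
constant within trait-equivalence classes, the class-constant subspace is
exactly invariant, and the collective spectrum reduces to a $K \times K$
eigenproblem (`K` classes) whose complement is the strictly stable
diagonal cluster — this reduction is verified against dense
eigendecomposition in the tests. The `"sample"` convention draws the
diagonal from the truncated-Gaussian law. The package defaults to
`"sample"` (averaged over draws) for classification because the
within-class abundance spread — and the spread of dynamical time scales it
induces — is precisely what lets microscopic randomness stabilize
collective oscillations; the mean convention collapses that spread and,
for example, declares the rescued two-group coexistence a saddle when
direct simulation shows a stable fixed point. The sampled convention
reproduces both the two-group stability and the many-groups stabilization
threshold.

## What the generators emulate, and what they do not

All experiments run on synthetic communities; the defaults are the study
conditions. The two-group showcase uses fractions $(0.75, 0.25)$ and
couplings $\bigl[\begin{smallmatrix}0 & -6\\ -2 &
0\end{smallmatrix}\bigr]$ — group 1 larger but less competitive — so that
structure alone excludes group 1, moderate randomness rescues it,
dominance reverses, and total diversity peaks at intermediate $\sigma$.
The quantitative theory-versus-simulation checks use a milder coexisting
pair (equal groups, couplings $-1.2$ and $-0.8$) at $S = 2000$ and
$\sigma = 0.5$, where all macroscopic observables are $O(1)$ and the 5%
agreement is meaningful. The many-groups stability analysis uses 15 groups
of 60 species: with 20 species per group, finite-size multistability (each
disorder realization having its own low-diversity attractors) obscures the
self-averaging transition the theory describes; 60 species per group
restores it at tractable cost, and the simulated transition is measured by
*continuation* (descending $\sigma$, reusing the final state) so that
simulation and theory track the same attractor branch.

None of the generators emulate real data: abundances are dimensionless,
growth rates and carrying capacities are identical across species, and
interactions are time-invariant. Passing tests show internal consistency
of theory and simulation under these conditions — not that any real
community satisfies them.

## Numerical choices and degenerate inputs

Problem sizes in the shipped tests were chosen so the whole suite runs in
tens of minutes on one core: $S = 2000$ (5 disorder seeds) for the
self-consistency check, $S = 4000$ (one seed) for the abundance-law check,
$S = 400$ (3 seeds, $\sigma$ grid step 0.05) for the bulk onset, and
$15 \times 60$ for the collective transition (grid step 0.1). Classifying
runs (fluctuating vs settling) use `rel_tol = 1e-6`; quantitative averages
use at most `1e-6` as well, where integration error is far below
finite-size scatter. Persistent fluctuation is distinguished from a slow
transient by a decay-ratio rule (late-window species variance above
$10^{-10}$ *and* at least 5% of the mid-window variance), because near a
transition both the fixed-point flag and any absolute variance threshold
misread critical slowing down.

Degenerate inputs are defined: zero-column trait tables give a
structureless community usable everywhere ($\mu = 0$, empty $f^\star$,
empty collective spectrum); $\gamma = 0$ states degrade the SAD to point
masses and make abundance sampling deterministic; a zero matrix decomposes
to an empty trait set.

## Known limitations

* The dynamical mean-field theory itself (two-time correlators, the
  self-consistent colored-noise process) is not solved numerically; only
  its equilibrium consequences are implemented, so out-of-equilibrium
  regimes are characterized by direct simulation and by where the
  equilibrium description fails.
* Cold starts of the self-consistency solver far from any branch can fail
  or land on unintended branches; continuation (`sigma_scan()`, or passing
  `init`) is the supported way to traverse $\sigma$ ranges.
* At mean-zero disorder past the bulk transition the model itself exhibits
  runaway growth at the sizes used here; the integrator reports it rather
  than chasing a finite-time singularity.
* The balanced-tree archetype violates $n_F \ll S$ by construction; its
  macroscopic predictions remain exact (the closed relations never assume
  low rank) but the low-rank decomposition utilities do not apply to it.
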