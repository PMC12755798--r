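# structglv

Tools for species-rich generalized Lotka–Volterra (gLV) communities whose
interactions superpose a **low-rank structural component** — built from
species traits mediated by a few collective functions (functional groups,
public goods, phylogenetic blocks) — and an **i.i.d. random component** of
tunable intensity. The package is aimed at theoretical community ecologists
who want to ask, for a concrete structured community, how much of the
phenomenology of fully disordered models survives, where species abundance
distributions pick up structure, and which of two distinct routes
(bulk-driven vs structure-driven) destabilizes equilibrium.

## The model

Rescaled abundances follow

```
dx_i/dt = x_i [ 1 − x_i + Σ_j A_ij x_j ] + m,        A_ij = μ_ij + σ z_ij /√S,
```

with a small immigration rate `m = 1e-8` keeping excluded species at a floor
from which they can re-invade. The structural part is a trait contraction

```
μ_ij = (1/S) Σ_λ 𝒮_i(λ) ℐ_j(λ),
```

where the impact trait `ℐ_i(λ)` is species *i*'s per-capita contribution to
collective function `f_λ = (1/S) Σ_i ℐ_i(λ) x_i` and the sensitivity trait
`𝒮_i(λ)` is the effect of that function on its growth. The random part has
i.i.d. zero-mean unit-variance entries `z_ij` (Gaussian or uniform) scaled by
`σ/√S`.

At equilibrium the macroscopic state is fully described by the function
magnitudes `f*` plus one disorder degree of freedom, the heterogeneity
`γ = σ √C*`, linked by the closed relations

```
f*_λ = (γ/S) Σ_i ℐ_i(λ) ω₁(x_i⁺/γ),      1 = (σ²/S) Σ_i ω₂(x_i⁺/γ),
```

with modal abundances `x_i⁺ = 1 + Σ_λ 𝒮_i(λ) f*_λ` and `ω_k` the k-th moment
of a unit Gaussian truncated at `−w`. Individual equilibrium abundances are
truncated Gaussians `x_i* = max(0, x_i⁺ + γ ξ_i)`, so the species abundance
distribution is an atom of extinct species plus a γ-blurred mixture centred
on the modal abundances, and the diversity is `φ* = mean ω₀(x_i⁺/γ)`.
Stability splits into a bulk criterion `φ*σ² = 1` (randomness-driven,
asynchronous species fluctuations) and the outlier eigenvalues of the
pseudo-Jacobian `𝒥 = −diag(x*) (I − μ)` (structure-driven collective
bifurcations, typically Hopf).

## What the package provides

* **Builders** (`group_structure`, `trait_structure`, `tree_structure`,
  `power_law_structure`, `many_groups_structure`, `decompose_structure`)
  for the structural archetypes, plus `interaction_system()` to superpose
  sampled randomness.
* **Simulator** `integrate_glv()` (deSolve-based, immigration floor,
  fixed-point detection) with diagnostics: `compute_functions()`,
  `extinction_census()`, `equal_time_correlator()`, `hilbert_embedding()`,
  `fluctuation_variances()`.
* **Equilibrium theory**: `solve_sigma_zero()` (support iteration),
  `solve_self_consistency()` (damped iteration + Newton continuation),
  `omega_k()`, `sad_density()`, and `simulate()` draws of equilibrium
  abundances from the truncated-Gaussian law.
* **Stability**: `bulk_index()`, `pseudo_jacobian()`, `outlier_spectrum()`
  (exact low-rank reduction on trait-equivalence classes),
  `classify_regime()`, `sigma_scan()`, `bulk_critical_sigma()`.
* **Showcases**: `run_two_group_demo()` (rescue of an excluded group,
  dominance reversal, non-monotone diversity) and `run_many_groups_demo()`
  (chaotic group turnover stabilized by intermediate within-group
  randomness).

## Worked example

```r
library(structglv)

## two competing functional groups, 2000 species, disorder sigma = 0.5
st <- group_structure(c(1000, 1000), rbind(c(0, -1.2), c(-0.8, 0)))
eq <- solve_self_consistency(st, sigma = 0.5)
eq
#> Macroscopic equilibrium (sigma = 0.5 )
#>   f* : 0.2718 0.3928
#>   gamma = 0.38439 | C* = 0.59103 | phi* = 0.9473
#>   residual 7.7e-10 (converged)

## direct simulation of one disorder realization
sys <- interaction_system(st, sigma = 0.5, seed = 1)
tr  <- integrate_glv(sys, sim_config(t_max = 400))
cen <- extinction_census(tr)
rowMeans(tr$functions[, tr$times > 200])   # simulated f: 0.2827 0.3800
cen$phi_sim                                # simulated diversity: 0.9765
```

The theory says: group 2 (more competitive) holds the larger biomass share
(`f2* = 0.39` vs `f1* = 0.27` on the species-averaged scale), about 95% of
species persist above the immigration floor, and within each group the
surviving abundances spread with width `γ ≈ 0.38` around the two modal
abundances. The single-realization simulation reproduces each number to a
few percent; `classify_regime(eq)` confirms the equilibrium is stable
(negative bulk index and collective spectrum).

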