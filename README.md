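# swarmcorr

Correlation, susceptibility and interaction range in insect swarms.

Midge swarms hover around a landmark with essentially no collective
order: their polarization is close to that of independent random walkers.
`swarmcorr` implements the quantitative chain needed to decide whether
such a disordered group is nonetheless a genuinely interacting, collective
system — and, if so, over what distance individuals perceive each other.

The package is aimed at people analysing 3D trajectories of animal groups
(movement ecology, collective behaviour, active matter): it takes
`frame,id,x,y,z` tables in metres plus a frame rate and body length, and
provides every estimator, null model and statistical test of the study as
reusable, tested functions.

## What it computes

* **Order parameters** per frame pair: polarization
  `Φ = |⟨v_i/|v_i|⟩|`, a rotational order `R = |⟨(L_i·K̂)/|L_i|⟩|` about
  the optimal (Kabsch) rotation axis `K̂`, and a dilatational order
  `Λ = ⟨cos(δv_i, y_i)⟩`, with a Monte-Carlo null band for an
  uncorrelated group (`E[Φ] ≈ √(8/3πN)`).
* **Dimensionless velocity fluctuations** `φ_i`: the individual velocity
  with the collective translation, optimal rotation and optimal
  dilatation subtracted, normalized so `(1/N)Σφ_i·φ_i = 1` and
  `Σφ_i = 0` exactly.
* **Connected correlation** `C(r) = Σ_{i≠j} φ_i·φ_j 1(r_ij∈bin) /
  Σ_{i≠j} 1(r_ij∈bin)`, its first zero `r0` (correlation length), the
  cumulative correlation `Q(r) = (1/N) Σ_{i≠j} φ_i·φ_j θ(r−r_ij)` and
  the susceptibility `χ = max_r Q(r)`. `Q(∞) = −1` exactly on every
  frame — a built-in self check.
* **Null and reference models**: the Non-interacting Harmonic Swarm
  (independent Langevin particles in a harmonic trap, Euler–Maruyama,
  stationary variance `T/k`) and a 3D Vicsek model with a central
  harmonic force (fixed speed `v0`, metric radius `rc`, spherical-cap
  noise `η`, compiled inner loop with an exact cell-list neighbour
  search), with density scans and finite-size scaling of the
  susceptibility peak.
* **Percolation**: largest-cluster fraction `n(λ)` by union-find, the
  threshold `λ_c` (smallest `λ` with `n ≥ θ`, default `θ = 0.6`), and
  the through-origin slope `s = λ_c/r1` across events.
* **Inference**: Spearman rank correlation with permutation P-values
  (`P = (1+#{|ρ_perm|≥|ρ|})/(m+1)`), the metric-vs-density comparison of
  `χ` against `r1/BL` and `r1`, the critical scaling fit
  `χ = a (x−x_c)^(−γ)` on the disordered branch with bootstrap
  intervals, and the combined interaction-range estimate
  `rc/BL = x_c · s` with delta-method error propagation.

`r1` is the mean nearest-neighbour distance, `BL` the body length.

## Worked example

```r
library(swarmcorr)

# a synthetic swarming event: disordered, but with correlated
# direction fluctuations of length ~0.45 m in a ~1 m group
traj <- correlated_trajectory(n = 150, n_frames = 10, L = 0.45,
                              speed = 0.08, fps = 10,
                              body_length = 0.002, seed = 1)
ev <- analyze_event(traj)
nb <- null_band(150, n_samples = 300, seed = 2)
nhs <- nhs_baseline_chi(nhs_config(n = 150, steps = 3000,
                                   transient = 2000, sample_every = 300,
                                   seed = 2))
```

This prints (via the analysis drivers, which run exactly this):

```
Polarization 0.070 +/- 0.026 (null band 0.079 +/- 0.032)
Rotational order 0.205, dilatational order -0.029
r0 = 0.625 m vs r1 = 0.184 m (ratio 3.4)
chi_swarm = 6.87 vs chi_NHS = 0.114 (ratio 60)
```

Reading: the polarization sits inside the uncorrelated null band — the
group has no collective order — yet the velocity fluctuations are
correlated over 3.4 nearest-neighbour distances and the susceptibility is
~60× the non-interacting baseline. Order and correlation are different
observables, and only the second reveals the interaction.

The numbered scripts under `analysis/` continue the study:
`03_vicsek_scan.R` locates the ordering transition of the Vicsek model
(`χ_max` grows 2.3 → 4.5 → 8.0 for n = 128, 256, 512 — the finite-size
signature of a critical point), `04_critical_fit.R` fits the scaling law
on the disordered branch (`x_c = 0.64 [−0.23, 1.50]`, `γ = 1.55`),
`05_percolation.R` shows `λ_c/r1` is density-invariant (slope
`s = 1.672 [1.600, 1.755]`), and `06_interaction_range.R` combines both
transition locators on Vicsek pseudo-events of known interaction radius,
recovering `rc/BL = 3.48 [−1.99, 8.95]` against a truth of 5 — wide on
purpose: with eight scattered events the nonlinear fit does not support a
sharp point estimate, and the interval is the honest summary.

## Layout

```
R/                  estimators, simulators, fixtures, pipeline
src/                Vicsek inner loop (Rcpp, cell-list neighbour search)
analysis/01..06     numbered drivers for the full study (write results/)
scripts/acceptance.R   headline quantities as JSON
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette: models, assumptions, choices
inst/extdata/       small synthetic pairwise-format example file
```
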