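---
title: "Correlation without order: methods behind swarmcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation without order: methods behind swarmcorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmcorr)
```

## The scientific question

Insect swarms look chaotic: unlike bird flocks, they have essentially no
collective order — the polarization of a midge swarm is close to what N
independent random walkers would produce. Does that mean the individuals
do not interact? Not necessarily. Order and correlation are different
things: a system can be globally disordered and still transmit behavioural
changes across the whole group, as a ferromagnet just above its critical
temperature does. `swarmcorr` implements the full quantitative chain
needed to ask this question of 3D trajectory data: mode subtraction,
connected correlation, susceptibility, null models, and the inference
layer that discriminates a metric interaction (fixed perception *distance*)
from a topological one (fixed *number* of neighbours) and converts the
observations into an interaction-range estimate.

## Velocity fluctuations and the collective modes

The raw velocity of individual i, `v_i(t) = (x_i(t+1) - x_i(t)) * fps`,
mixes the individual's behaviour with whatever the group is doing as a
whole. Three collective modes are removed sequentially for each
consecutive-frame pair:

1. **Translation** — subtract the centre-of-mass velocity.
2. **Rotation** — the proper orthogonal matrix best mapping the centred
   configuration at t onto the one at t+1, by the SVD-based least-squares
   superposition (with the determinant correction that excludes
   reflections). We do not iterate a joint refit of the three modes; the
   sequential order translation -> rotation -> dilatation is fixed.
3. **Dilatation** — the scalar `alpha` minimizing
   `sum |y(t+1) - alpha R y(t)|^2`, in closed form.

The residual `delta v_i` is made dimensionless as
`phi_i = delta v_i / sqrt((1/N) sum_k |delta v_k|^2)`. Two identities
follow exactly and are asserted throughout the test suite:
`sum_i phi_i = 0` (translation subtraction is a linear centring) and
`(1/N) sum_i phi_i . phi_i = 1` (the normalization). They matter because
they pin the large-distance behaviour of the cumulative correlation (below)
and make values comparable across swarms, species, and models without any
per-dataset normalization knob.

Degenerate inputs: a frame pair whose residual field is identically zero
(pure rigid motion) has no dimensionless fluctuation and is skipped, with
a count reported. The rotation fit refuses collinear configurations
(rank-deficient cross-covariance); frames with N < 4 are skipped for the
rotational and dilatational order parameters because the axis is too
poorly constrained.

## Order parameters

* **Polarization** `Phi = |(1/N) sum v_i / |v_i||`: 1 for a perfectly
  aligned group, of order `sqrt(8/(3 pi N))` for independent headings
  (the closed-form mean of the norm of a sum of random unit vectors, which
  the Monte-Carlo null band in `null_band()` reproduces).
* **Rotational order** `R = |(1/N) sum m_i|` with
  `m_i = (L_i . K)/|L_i|`, where `L_i` is the angular momentum of the
  translation-subtracted fluctuation about the Kabsch rotation axis `K`
  and the position is projected orthogonal to `K`. A coherent rotation
  gives `m_i = +1` for every individual, hence `R = 1`; incoherent motion
  mixes signs. The normalization by `|L_i|` (rather than a radius- or
  speed-weighted variant) is a design choice: it makes `R` a pure
  *coherence* measure, insensitive to where the fast individuals sit.
* **Dilatational order** `Lambda = (1/N) sum cos(angle between dv_rot,i
  and y_i)`, using the rotation-subtracted fluctuation: +1 coherent
  expansion, -1 coherent contraction. Using the rotation-stage (not the
  fully subtracted) fluctuation is deliberate — after dilatation
  subtraction a coherent expansion would be invisible by construction.

## Correlation, correlation length, susceptibility

The connected correlation is the binned pair average
`C(r) = sum_{i!=j} phi_i . phi_j 1(r_ij in bin) / sum_{i!=j} 1(...)`,
self-pairs excluded. Estimator choices:

* bin width `delta r` defaults to (max pair distance)/50 per frame, a
  compromise between resolution and per-bin counts; every user-facing
  function accepts an override;
* empty bins are reported as absent (`NA`), never as zero — a zero would
  bias the first-zero search;
* the correlation length `r0` is the first zero crossing, located by
  linear interpolation between the straddling populated bin centres (a
  curve that starts non-positive returns the first populated bin's lower
  edge; a curve that never crosses reports `NA` with the curve available
  for inspection).

The cumulative correlation
`Q(r) = (1/N) sum_{i!=j} phi_i . phi_j theta(r - r_ij)` integrates both
the span and the intensity of the correlation; its maximum over r is the
susceptibility `chi`. Two structural facts are used as self-checks: the
normalization identities force `Q(r -> infinity) = -1` exactly on every
frame, and because `dQ` across a bin has the sign of `C` in that bin, the
argmax of Q coincides with the first zero of C up to one bin whenever the
crossing is clean. Event-level `chi` is the time average of per-frame
values, with the standard deviation over frames as its error bar.

## The two reference models

**Non-interacting Harmonic Swarm (NHS).** Independent Langevin particles
in a 3D harmonic trap, `m dv = (-gamma v - k x) dt + sigma sqrt(dt) xi`,
integrated by Euler-Maruyama with a stability guard
(`gamma dt / m < 2`). The noise amplitude is tied to the friction by the
fluctuation-dissipation form `sigma = sqrt(2 gamma T)`, so the stationary
positional variance is `T/k` per component — the analytic oracle the tests
use. Defaults: `m = k = T = 1`, critically damped
`gamma = 2 sqrt(mk)`, `dt = 0.01 sqrt(m/k)`; with these the displacement
per integration step is a few percent of the nearest-neighbour distance,
in the qualitative regime of a real acquisition. The NHS looks like a
swarm (it hovers around the origin, disordered) but its C(r) is
structureless and its chi is small and density-independent; it is the
null hypothesis "everyone interacts only with the marker".

**Vicsek model in a central potential.** Self-propelled particles at fixed
speed `v0` align with all neighbours within a metric radius `rc` (self
included), feel a harmonic pull `-beta x` towards the origin (which also
provides cohesion, so boundaries are open), and suffer directional noise:
the new heading is drawn uniformly from the spherical cap of solid angle
`4 pi eta` around the deterministic direction (`eta = 1` erases all
alignment — the tests verify the polarization then matches the
independent-heading null band). The inner loop is compiled (Rcpp) with a
flat cell-grid neighbour search of cell size `rc`; the grid is exact, is
verified bit-for-bit against a brute-force path, and falls back to brute
force when the bounding box is too sparse for a grid to pay off. All
randomness flows through R's RNG, so runs are bit-reproducible under
`set.seed()`.

The control parameter of the ordering transition is `x = r1/rc`. We tune
the density (hence `x`) through `beta`. The simulation protocol mirrors
standard practice — a transient, then configurations sampled at intervals
long enough that fluctuations decorrelate. The scans used in the tests
and analysis scripts run n in {128, 256, 512} with 30 sampled
configurations after a 3500-step transient; these sizes keep the full
suite within minutes on one core while still bracketing the
susceptibility peak at every size.

## Percolation and the interaction range

For a point set, link every pair closer than `lambda` (strictly) and track
the largest-cluster fraction `n(lambda)` — a step function with jumps only
at pairwise distances, computed by a single sorted union-find sweep. The
percolation threshold `lambda_c` is the smallest scale where
`n >= theta`, located on a 40-point grid and refined by bisection to a
relative 1e-3. The default `theta = 0.6` is a package choice; because the
percolation transition is sharp, the threshold moves little with `theta`
(the sensitivity is reported by the curve itself). Across Poisson point
sets spanning a 125-fold density range, `lambda_c / r1` is constant to a
few percent (~1.7), so a single through-origin slope `s` summarizes the
geometry.

The interaction-range argument combines two independent transition
locators: the critical fit of `chi = a (x - x_c)^(-gamma)` against
`x = r1/BL` gives the transition nearest-neighbour distance in body
lengths; the percolation slope says the group stops being connected — and
hence cannot order — when `r1` exceeds about `rc / s`. Eliminating the
transition `r1` gives `rc/BL = x_c * s`, with delta-method propagation of
the two confidence intervals.

## Statistical layer: choices and guards

* **Permutation test.** Spearman rho (average ranks for ties) with a
  two-sided criterion on |rho| and the small-sample correction
  `P = (1 + #{|rho_perm| >= |rho_obs|})/(m + 1)`; never zero, uniform
  under the exchangeable null (KS-checked in the tests). Default
  `m = 10000`. When two variables are compared against the same response
  (chi vs `r1/BL` and vs `r1`), both tests run on the same permutation
  set so that a degenerate rescaling (constant body length) gives
  *identical* P-values rather than merely similar ones.
* **Critical fit.** Least squares on `log chi` with the transition point
  profiled out (the model is linear in `log a` and `gamma` at fixed
  `x_c`), a coarse multi-start over `x_c` below the data range, 1D
  refinement, then a Levenberg-Marquardt polish. Confidence intervals are
  a bootstrap over points: with scattered field data the fit is
  genuinely unstable, and an interval is the honest summary.
  Two guards precede any fit: the susceptibility must *decrease* with x
  (otherwise the data are not on the disordered branch), and the
  decreasing trend must be significant under the package's own
  permutation test (P < 0.05). The second guard is what makes the
  pipeline decline to report a transition when fed non-interacting
  (NHS) events whose chi-vs-x scatter is pure noise — without it, a
  power law can always be threaded through noise with `x_c` drifting to
  an arbitrary point below the data.
* **Through-origin percolation fit** for `lambda_c` vs `r1`, because the
  relation is a pure proportionality (both quantities vanish together);
  bootstrap-over-events CI.

## What the synthetic generators emulate — and what they do not

* `planted_mode_swarm` plants exact translation/rotation/dilatation
  between two frames plus centred Gaussian residuals: ground truth for
  the decomposition, including the zero-noise identity case.
* `correlated_swarm` builds a direction-fluctuation field with a tunable
  correlation length L: the positions are partitioned into spatial blobs
  of radius about L (k-means on the positions), each blob shares a random
  unit vector, isotropic noise is added, and the field is re-centred and
  normalized so it satisfies the exact constraints the estimators assume.
  The blob construction was preferred to a Gaussian random field because
  its planted length scale is unambiguous; the recovery bands used in the
  tests (e.g. chi ordered in L for L = 0.2, 0.4, 0.8 at n = 200,
  noise 0.25) were calibrated by oracle pre-runs of the generator itself.
* `correlated_trajectory` chains such fields into a multi-frame event so
  the pipeline runs end to end on a field-format input.
* `poisson_swarm` gives uniform points at fixed density for the
  percolation analysis.

None of these imitate midge flight kinematics — accelerations, pair
manoeuvres, marker attraction. Passing tests therefore demonstrate that
the estimators measure what they claim on data with known structure, not
that real swarms behave like the fixtures.

## Known limitations

* Velocities are forward differences of consecutive frames; tracking gaps
  are excluded from the affected frame pairs, never interpolated.
* Equal-time correlations only; no spatio-temporal correlation functions.
* The interaction-range estimate inherits the assumptions of both the
  critical fit (one-sided data near a presumed transition) and the
  percolation argument (an equilibrium-style connectivity criterion); it
  is a consistency estimate, not a direct measurement.
* The Vicsek scans in the shipped scripts are scaled down (n <= 512);
  exponents from such sizes carry visible finite-size bias, which is why
  the finite-size-scaling output is a parametric peak curve rather than a
  single exponent claim.

## A minimal session

```{r example, eval = FALSE}
traj <- correlated_trajectory(n = 150, n_frames = 10, seed = 1)
ev <- analyze_event(traj)
print(ev)

nhs <- nhs_baseline_chi(nhs_config(n = 150, seed = 2))
ev$chi / nhs$mean   # how far above the non-interacting baseline?
```

The numbered scripts under `analysis/` run the complete study — order
parameters, correlation vs NHS, Vicsek scans with finite-size scaling,
the critical fit, percolation, and the combined interaction-range
estimate — writing their tables under `results/`.
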