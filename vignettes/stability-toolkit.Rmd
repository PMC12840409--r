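---
title: "Peak-map and monodromy stability analysis: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-map and monodromy stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(peaknet)
```

## The models

### From flow to map

The Lorenz field `F(x, y, z) = (sigma(y - x), x(rho - z) - y, xy - beta z)`
with `sigma, rho, beta > 0` is dissipative (constant divergence
`-(sigma + 1 + beta)`) and, at the classical parameters
`sigma = 10, rho = 28, beta = 8/3`, chaotic. Recording the successive local
maxima `z_n` of one coordinate collapses the flow onto the one-dimensional
*peak map* `P : z_n -> z_{n+1}`, a Poincare-style reduction in which the
section is defined by `dz/dt = 0, d2z/dt2 < 0` rather than by a geometric
plane. Cycles of `P` correspond to periodic orbits of the flow; the local
stability of a T-cycle is governed by the chain-rule multiplier
`Lambda_T = prod P'(z_j)`, with `|Lambda_T| < 1` attracting,
`|Lambda_T| > 1` repelling, and `|Lambda_T| = 1` undecidable at linear
order (saddle-node or period-doubling boundaries).

### From map to network

Two discrete neural systems sit on the other side of the toolkit.

The **Kropotov-Pakhomov network** is a fully connected binary-threshold
population: potentials `P_i` decay at rate `alpha`, receive the synaptic
drive, drop by `beta` after a spike, and threshold into activities
`N_i = theta(P_i - h_i)` with `theta(x) = 0` for `x <= 0`. Synaptic
efficacy is the sum of a fast activator and depressant pair
`x_i1, x_i2` (linear recurrences with rates `A1, A2` and drives
`B N + C`), and the base weights follow the delayed Bogdanov-Hebb rule
`W0(k+1) = (1 - mu) W0(k) + upsilon sum_m N_i(k) N_j(k - m)`. The
*modified* variant divides the drive by the active presynaptic count plus
one; this divisive normalization bounds the drive by `G_max W_max`
independently of network size, which is the structural reason the modified
network cannot blow up while the raw-sum original can.

The **MRNN** is the smooth continuous-state counterpart
`x_{n+1} = (1 - gamma) x_n + eta W tanh(x_n) + b` with `rho(W) = 1`, whose
Jacobian `J(x) = (1 - gamma) I + eta W diag(1 - tanh^2 x)` yields the
monodromy matrix `M_T` along a T-orbit. `rho(M_T) < 1` plays exactly the
role `|Lambda_T| < 1` plays for `P`; when the operator carries a
one-dimensional invariant manifold conjugate to `P` with contracting
transverse directions, the two verdicts coincide (see the embedding
harness below).

## Parameters and defaults

| parameter | default | meaning / rationale |
|---|---|---|
| `sigma, rho, beta` | 10, 28, 8/3 | classical chaotic Lorenz regime |
| `h` | 0.01 | resolves the ~0.7-time-unit inter-peak spacing with ~70 samples |
| `A1, A2, B1, B2, C1, C2` | 0.4, 0.2, 0.2, 0.5, 0.2, 0.1 | efficacy constants; at rest (`N = 0`) the summed efficacy settles on exactly 1 |
| `mu, upsilon` | 0.001, 0.1 | slow weight decay and Hebb gain; sustained coincidence saturates at `upsilon / mu = 100` |
| `alpha, beta` (KP) | 0.1, 0.5 | not fixed by the efficacy constants; chosen so unstimulated potentials decay and stay sub-threshold while a stimulated network can sustain recurrent activity. Exposed in `kp_params()` |
| `h_i` | 0 | thresholds are required non-negative; zero is the least restrictive admissible choice |
| `delays` | {1} | the single-delay rule; arbitrary sets supported |
| `eta, gamma` | 0.9, 0.25 | mid-range gain at the dissipation used by the eta-sweeps |
| `m` | 64 | operator dimension at which the emulation diagnostics are reported |

Two textual ambiguities in the network equations were resolved as follows
(both choices are the ones under which the boundedness analysis goes
through): the synaptic sum runs over the *presynaptic* index `j` in both
numerator and denominator of the normalized drive, and the threshold
function applies to `P_i(k) - h_i` (thresholds shift potentials, they are
not delays).

## Numerical choices

* **Norms.** All stopping rules (midpoint fixed-point iteration,
  step-doubling error) use the max-norm over state components: it is
  dimension-independent and the strictest of the usual choices.
* **Implicit midpoint.** Iteration seeded with the current state, stopped
  at `1e-12`, capped at 50 iterations — generous, since the iteration
  contracts geometrically whenever `h L / 2 < 1`, and the cap is hit only
  when that condition fails (reported as non-convergence, not silently).
* **Adaptive control.** The controller step is
  `h (tau / eps)^(1/(p+1))`, clipped to `[h_min, h_max]` and to at most
  x5 growth per step (guarding the division by a near-zero error
  estimate). The raw controller lands exactly on the acceptance boundary
  `eps = tau`, where it cannot make progress; the rejection loop in
  `adaptive_advance()` therefore retries at 0.9 times the proposed step, a
  standard safety backoff, while `adaptive_step()` itself stays exactly
  proportional.
* **Divergence guard.** Integration aborts when any coordinate exceeds
  `1e6`: the Lorenz attractor is bounded, so escape of that magnitude is a
  scheme failure, not dynamics.
* **Peak refinement.** A 3-point parabola through the samples around a
  discrete maximum; exact for quadratic data and convergent at the
  integrator's order for smooth flows. Plateaus of more than two equal
  samples are flagged degenerate and left unrefined. For series produced
  by genuine maps (logistic iterates, MRNN readouts) refinement is off:
  interpolating between iterates has no meaning. The scanned coordinate
  defaults to `z` but `x` is equally supported — both sections appear in
  practice and neither is canonical.
* **Cycle search.** Roots of `P^T(z) - z` on a 512-point bracketing grid,
  refined by bisection to `1e-10`. A one-humped map keeps the root count
  per bracket at one, so brackets suffice. A T-cycle is reported only at
  its minimal period (divisor check within 100x the root tolerance), and
  an iterate that is identity-like on more than half the grid raises a
  degenerate-map flag instead of reporting every grid point as a root.
* **Marginality.** `||Lambda| - 1| < 1e-6` is labelled `marginal`: the
  linear criterion is genuinely silent there.
* **Regime classifier.** Defaults `epsilon = 1e-3` of the observed height
  range, majority threshold `theta = 0.8`, `T_max = 12`. Candidate periods
  get their multiplier from windowed least-squares slopes (window 5% of
  the height range) chained around the candidate nodes. When the orbit
  has already collapsed onto a cycle to machine precision the slope fit is
  degenerate; such perfect recurrence is treated as attracting with the
  multiplier recorded as `NA` — the alternative (rejecting the period the
  data repeats exactly) would be absurd. A candidate with contracting
  multiplier is `periodic_stable` when its recurrence fraction is
  essentially exact (`r_T >= 0.99`) and `non_periodic_stable` otherwise.
* **Lyapunov estimation.** Benettin-style QR re-orthonormalization every
  10 steps (exponents are insensitive to doubling or halving that
  interval); natural logarithms throughout. The `lambda_2 ~ 0` acceptance
  band is +-0.02 per unit time, the finite-time estimator noise at an
  averaging horizon of 2x10^3 time units. The spectral-radius cross-check
  uses the tail Gelfand estimate `(||M^k|| / ||M^{k/2}||)^{2/k}`, which
  cancels the norm's non-normal transient prefactor; the plain
  `||M^k||^{1/k}` converges only like `1/k` and would need far larger `k`
  for the same accuracy.
* **Readout and teacher forcing.** The readout regression is solved by
  SVD with a minimum-norm fallback (flagged) on rank deficiency. Teacher
  forcing uses the target state `x_tar = x_n + (P(y_n) - y_n) c` — the
  minimum-norm state shift whose readout equals the target map value —
  inside the dissipative outer-product update, with `W` renormalized to
  spectral radius 1 whenever it drifts outside `[0.8, 1.2]`. The default
  learning rate `0.005` is small enough that the monitored one-step error
  descends monotonically until it reaches the noise floor; larger rates
  oscillate.
* **Sweeps.** Burn-in 2000 steps and 200 recorded peaks per grid value;
  distinct peak heights are counted with an absolute tolerance of `1e-4`
  of the per-column range (or of the whole-diagram range when columns are
  compared against each other, as in the rho-sweep, where an equilibrium
  column must not be inflated by its own microscopic spread).
* **Grid search.** The binary network has no smooth Jacobian, so the
  "spectral" pruning rule uses an empirical proxy: the geometric-mean
  per-step amplification of a small initial-potential perturbation
  between twin runs, rejected above 1.05. The objective weights
  `(alpha, beta, gamma)` of `J = alpha sigma_x + beta sigma_e + gamma D_W`
  default to `(1, 1, 1)`; they are balancing coefficients with no
  canonical values, exposed as arguments.
* **Size selection.** `C(m) = (m / max(M))^2` (parameter-count
  proportional), penalty weight 0.05. Candidates must pass a Lyapunov-gap
  and a Hausdorff-distance gate before the score is compared; when no
  candidate passes — which is the honest outcome for an untrained operator
  against a specific target map — the full ranking is still returned with
  `m_star = NA` rather than silently promoting the least-bad candidate.

## The embedding harness and the transverse assumption

The stability-correspondence statement for an operator conjugate to `P` on
an invariant 1D manifold comes with a transversality assumption that can
be read two ways: transverse eigenvalues *outside* the unit circle (which
would make the manifold normally repelling, and under which the full
spectral radius could not equal `|P'(u*)|`), or transverse eigenvalues
*dominated* by the tangential one. `conjugate_embedding_test()` builds the
block system `F(x) = (P(x_1), lambda_2 x_2, ...)` where both readings can
be exercised directly: with contracting transverse rates the verdicts from
`|P'(u*)|` and `rho(DF)` agree on every case; with an expanding transverse
rate the spectral radius is set by the transverse part, the biconditional
breaks, and the report flags the violation instead of asserting either
reading.

## What the synthetic generators emulate — and what they do not

All test inputs are generated in code: logistic orbits stand in for the
empirical peak map (they share the one-humped geometry, closed-form cycles
and multipliers, and the `ln 2` chaotic exponent at `r = 4`), short Lorenz
trajectories exercise the integrators on a genuinely chaotic field, tiled
binary blocks give activity histories with exactly known periods, and
planted cycles with Gaussian jitter probe the recurrence profile's
tolerance behaviour. What these fixtures deliberately lack: measurement
noise on the flow, non-stationarity, multiple extrema per oscillation,
and any empirical neural recording. Passing tests therefore demonstrate
correctness of the operations and their closed-form limits, not
performance on noisy laboratory data.

Default study conditions follow the stated protocols: 64 neurons,
stimulation of one random neuron per step at amplitude 0.5 for the first
2000 steps, and the documented sweep grids (`rho` in `[20, 36]`, `eta` in
`[0.2, 1.6]` at `gamma = 0.25`, `gamma` in `[0.0, 0.9]`). At the default
constants the stimulated network settles into a fully active saturated
state — bounded, as the normalization guarantees, but dynamically trivial;
the regime machinery is therefore validated on constructed histories with
known structure as well.

## Problem sizes used by the shipped tests

Chosen to keep the whole suite around ninety seconds while leaving every
estimate comfortably inside its tolerance: integrator-order slopes from a
1-time-unit segment started on the attractor with steps
`0.02/0.01/0.005/0.0025` (the asymptotic regime; transient segments off
the attractor show inflated RK4 slopes); Lyapunov averaging over
2x10^3 time units after 10^3 of burn-in for the middle-exponent band, and
200 time units for the (fast-converging) exponent sum; 10^5 steps for the
64-neuron boundedness run; 10^4 steps for the plasticity ablation; 60 grid
points for the eta-sweep; 200 random cases for the embedding harness.

## Known limitations

* The peak-map reduction assumes one extremum per oscillation; flows with
  secondary maxima need a stricter section than the sign test used here.
* The regime classifier estimates multipliers from finite orbit data; on
  an orbit that converged generations ago the multiplier is unrecoverable
  (reported as `NA`, see above).
* `lambda_2 ~ 0` is a finite-time estimate; the +-0.02 band is empirical,
  not a confidence interval.
* The grid-search spectral proxy measures one perturbation direction over
  one horizon; it prunes gross instability but is not a Jacobian
  spectrum.
* The untrained MRNN at the default `(eta, gamma)` does not quantitatively
  emulate a given target map (the size-selection gates say so); the
  correspondence it illustrates is qualitative — the shared
  fixed-point/periodic/chaotic hierarchy under its own control
  parameters.
* Lattice-coupled (spatially extended) discretizations and symplectic or
  exponential integrators are out of scope.
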