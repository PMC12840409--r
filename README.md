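# peaknet

Stability analysis of discrete Lorenz dynamics through the one-dimensional
peak map, and of Hebbian recurrent networks through the monodromy matrix —
two sides of the same multiplicative stability criterion.

## The problem

A chaotic flow such as the Lorenz system

    dx/dt = sigma (y - x),   dy/dt = x (rho - z) - y,   dz/dt = x y - beta z

can be reduced to a one-dimensional return map by recording successive local
maxima of one coordinate: the *peak (vertex) map* `P : z_n_max -> z_{n+1}_max`.
Periodic orbits of the flow become cycles of `P`, and a T-cycle
`{z_0, ..., z_{T-1}}` is locally asymptotically stable exactly when its
*multiplier*

    Lambda_T = prod_{j=0}^{T-1} P'(z_j)

satisfies `|Lambda_T| < 1`. For a multidimensional discrete operator
`x_{k+1} = F(x_k)` the analogous object is the *monodromy matrix*
`M_T = J_{T-1} ... J_1 J_0` (the ordered product of Jacobians along the
orbit), with the criterion `rho(M_T) < 1` on its spectral radius. When the
operator carries an invariant 1D manifold conjugate to `P`, the two criteria
coincide — which makes a recurrent network a usable *emulator* of the flow's
stability structure.

`peaknet` implements the full stack around that correspondence:

* **Integration** — Lorenz field with explicit Euler, classical RK4, and the
  implicit midpoint rule (fixed-point iteration), linear stability gains
  `R(z)`, step-size criteria, and step-doubling adaptive control.
* **Peak map** — peak detection with 3-point quadratic refinement, empirical
  successor pairs, windowed slope estimates of `P'`, cycle finding with
  minimal-period deduplication, multiplier-based classification, and a
  recurrence-based regime classifier.
* **Lyapunov diagnostics** — QR (Benettin-style) spectra for maps and flows,
  discrete/continuous exponent rescaling, Kaplan-Yorke dimension.
* **Kropotov-Pakhomov network** — the original and the divisively
  normalized binary-threshold network with plain and delayed Bogdanov-Hebb
  plasticity, stimulation protocols, periodic-regime closed forms, regime
  reports, and block-frequency profiles.
* **Recurrent emulator (MRNN)** — the operator
  `x_{n+1} = (1 - gamma) x_n + eta W tanh(x_n) + b` with spectral-radius-1
  `W`, its Jacobian and monodromy analysis, least-squares readout fitting,
  Hebbian teacher forcing toward a 1D target map, bifurcation sweeps in
  `eta` and `gamma`, parameter grid search, network-size selection, and a
  harness for the conjugate-embedding stability correspondence.

## Worked example

```r
library(peaknet)
p <- lorenz_params(sigma = 10, rho = 28, beta = 8/3)
traj <- integrate_system(c(1, 1, 1), function(s) lorenz_field(s, p),
                         h = 0.01, n_steps = 20000, scheme = "rk4", params = p)
traj
#> Discrete trajectory: 20001 states, dim 3, h = 0.01, scheme = rk4

peaks <- detect_peaks(traj, coord = "z")
peaks
#> Peak sequence: 270 peaks of coordinate 'z'

classify_regime(peaks)
#> Regime: non_periodic_unstable
```

The chaotic Lorenz orbit yields 270 z-maxima in 200 time units and no
recurrent period up to `T_max = 12` whose empirical multiplier is
contracting — the regime classifier reports an aperiodic, unstable peak map.
Against an analytic one-humped map the cycle machinery is exact:

```r
cycles <- find_cycles(logistic_map(3.2), c(0, 1), T_max = 2)
cycles[[3]]$points
#> [1] 0.5130445 0.7994555
cycles[[3]]$multiplier
#> [1] 0.16
```

These are the closed-form 2-cycle `(r + 1 +- sqrt((r+1)(r-3))) / (2r)` and
its multiplier `-r^2 + 2r + 4 = 0.16`; `|0.16| < 1` marks the cycle stable.
The Lyapunov spectrum of the flow quantifies the same picture globally:

```r
spec <- lyapunov_flow(function(s) lorenz_field(s, p),
                      function(s) lorenz_jacobian(s, p),
                      x0 = c(1, 1, 1), h = 0.01, t_total = 500, burn_in = 100)
spec
#> Lyapunov spectrum (per_time):   0.9060447,  -0.0059141, -14.5666948
kaplan_yorke(spec)
#> [1] 2.061794
```

One expanding direction, one neutral (flow) direction, strong contraction,
and a fractal attractor dimension just above 2.

A command-line front end (`inst/cli/peaknet`) exposes the same operations as
subcommands (`simulate`, `peaks`, `classify`, `sweep_rho`, `kp_run`,
`lyapunov`, `mrnn_sweep`, `fixtures`) driven by `run_config()`, which writes
a manifest with output hashes for exact reruns.

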