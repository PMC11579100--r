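---
title: "Penalty methods for optimal dosing under state constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalty methods for optimal dosing under state constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optidose)
```

## The optimal dosing task

A PK/PD model is a parameter- and dose-dependent ODE system
$\dot y = f(t, y, \theta, D)$, $y(t_0) = y^0(\theta)$, on a horizon
$[t_0, t_f]$, with the model parameters $\theta$ estimated beforehand and
held fixed. The doses $D = (D_1, \dots, D_m)$ are administered at fixed
times according to a dosing scenario; they are the only free variables.
Therapeutic goals split into a top-priority target, encoded as a *state
constraint* $g(y(t, D)) \le 0$ on a window $[t_1, t_2]$, and a secondary
target, encoded as a *cost functional* $J(D)$ to be minimized. Doses whose
trajectory satisfies the constraint are called feasible.

All constraints are normalized to $g \le 0$: a lower bound
$N \ge 1$ becomes $g = 1 - N$, an upper bound $B \le B_{tar}$ becomes
$g = B - B_{tar}$, so one penalty code path serves every direction. Four
constraint kinds are supported:

* **path** — $g \le 0$ pointwise on a window;
* **point** — $g \le 0$ at a single time (the window degenerates to a
  point and the penalty integral to a single evaluation);
* **mean value** — the windowed average of an observable is bounded;
* **duration** — the accumulated time an observable spends below a level
  is bounded, via the auxiliary state
  $\dot\tau = \mathbf 1\{N(t) < \ell\}$, $\tau(t_0) = 0$.

## Penalty transformation and continuation

The state-constrained problem is replaced by box-constrained minimization
of $J(D) + P(D, \rho)$ with the quadratic penalty
$P(D, \rho) = \tfrac{\rho}{2}\int_{t_1}^{t_2}\max\{0, g\}^2\,dt$. The
penalty vanishes exactly on feasible trajectories and grows with the
violation, so minimizers of the penalized problem approach the constrained
optimum as $\rho \to \infty$. In practice a short geometric schedule
(default: one decade per stage, e.g. $\rho \in \{10, 10^2, 10^3, 10^4\}$)
is run with warm starts; the report column $PFV/\rho$ is a $\rho$-free
violation measure that must tend to zero, and a final value above
$10^{-6}$ per unit window length triggers a warning that the penalty
parameter needs to be increased further.

Cost and penalty values are not post-processed from a stored solution:
they ride along the integration as *augmented quadrature states*
$\dot y_{CF} = W(t)$, $\dot y_{PF} = \tfrac{\rho}{2}\max\{0, g\}^2$ (zero
outside the window, zero initial values), exactly as one accumulates an
AUC. This keeps a single ODE solve per objective evaluation and lets the
solver control quadrature error together with state error. An independent
dense-output trapezoid route implements the same quantities for
verification; the test suite cross-checks the two.

The augmented-Lagrangian variant replaces the quadratic penalty by the
Powell–Hestenes–Rockafellar function
$P_{AL}(D, \lambda, \rho) = \tfrac{1}{2\rho}\int \max\{0, \lambda(t) +
\rho g\}^2 - \lambda(t)^2\,dt$ with a nonnegative multiplier function
$\lambda$, implemented exactly in this printed form; $\lambda = 0$
reduces it to the quadratic penalty, and the package exploits that
identity both as a test invariant and to make the frozen-multiplier loop
bitwise identical to plain continuation. The outer loop applies the
standard first-order update
$\lambda^+ = \min\{\max\{0, \lambda + \rho\, g(y(\cdot, D^*))\},
\lambda_{max}\}$ pointwise (cap $\lambda_{max} = 10^6$ with
reset-on-divergence, since the multiplier-update literature leaves the
safeguard rule open); $\lambda$ is stored as a piecewise-linear function
on a grid over the constraint window (default 51 points), a choice that
is itself open — any dense enough discretization works, and the toy
problems confirm convergence of $\lambda$ to the analytic Lagrange
multiplier.

## Simulation of dosing events

Administrations are resolved into events before simulation. In
dose-optimization mode each record contributes one event of amount
$F \cdot D_{\text{group}}$ (bioavailability times the group's optimized
dose); in interval-optimization mode amounts are fixed and the record of
group $g$ is placed at $\theta (g-1)$ — the lag-time construction that
turns the administration time of the next dose into the optimized
parameter. Boluses are instantaneous state jumps applied by the
simulator; infusions contribute a zero-order rate amount/duration through
the input vector $u$ passed to the right-hand side. Integration
(`deSolve::lsoda`) restarts at every event time, infusion endpoint,
constraint-window endpoint and support time, so no discontinuity ever
falls inside a solver step. Default tolerances are deliberately tight
(rtol $10^{-10}$, atol $10^{-12}$; both exposed) because the optimizer
differentiates the objective by central finite differences with relative
step $10^{-6}$ — quadrature noise must sit well below the differencing
step. The heavier test and acceptance runs use rtol $10^{-8}$ / atol
$10^{-10}$ and a 150-point reporting grid, still several orders below the
asserted tolerances.

The duration state is discontinuous in its integrand. The default
evaluation is therefore *exact*: threshold crossings of the dense output
are located by piecewise-linear inversion and the below-threshold time is
summed, rather than integrating the indicator through the stiff solver. A
logistic surrogate $1/(1 + e^{(N-\ell)/\varepsilon})$ (default
$\varepsilon = 0.01$ observable units) is available when a smooth
augmented state is preferred inside the optimizer, as is the
area-below-threshold alternative $\int \max\{0, \ell - N\}\,dt$, which
behaves best numerically; the non-smooth indicator is a known source of
premature optimizer termination.

## The optimizer

The box-constrained solves use a projected quasi-Newton method
(`L-BFGS-B`) with central finite-difference gradients (per-coordinate
step $10^{-6}\max(|D_i|, 1)$, one-sided at active bounds), stopping at a
relative objective change of $10^{-5}$ — five significant digits, the
accuracy customarily requested from estimation runs of this kind. Because
$\max\{0, g\}^2$ is $C^1$ but not $C^2$, the line search can stall on the
constraint-activity kink; the solver then restarts once from the best
point seen and reports a stall within tolerance as such. Feasible initial
doses are recommended and infeasible starts produce a warning: a large
violation under a large $\rho$ yields penalty values that dominate the
objective and strain the ODE solver. An optional pre-phase that minimizes
the total penalty alone until feasibility is deliberately not enabled by
default. Multi-start dispersion is the diagnostic for non-uniqueness
(too many free doses for too few targets); the remedy — grouping doses so
the same dose is administered at several time points — is left to the
problem definition.

For one- and two-parameter problems a brute-force `grid_oracle()`
(exhaustive grid plus golden-section refinement) provides an independent
verification route; the test suite requires solver/oracle agreement
within 0.1 dose units on every bundled 1-D problem.

## Bundled problems and what the synthetic models do (not) show

The packaged disease examples use canonical model *structures* with
**synthetic parameter values**, chosen once so that each task is
well-posed and then frozen:

* **Tumor/myelosuppression** (days): transit-compartment tumor-kill model
  (saturating growth $2\lambda_0\lambda_1 x_1 / (\lambda_1 + 2\lambda_0
  x_1)$, kill $k_2 C x_1$, three damage transits, tumor weight
  $W = \sum x_i$) coupled to the five-state Friberg cascade (feedback
  $(\mathrm{Circ}_0/\mathrm{Circ})^\gamma$, linear drug effect
  $E = 0.12\,C$, baseline 7). Sixteen daily IV boluses on days 12–27 in
  four groups of four consecutive days; minimize $\int_{12}^{32} W\,dt$
  subject to $N \ge 1$ on $[12, 32]$, bounds $[0, 300]$, feasible start
  $D = 10$ per group, schedule $\{10, 10^2, 10^3, 10^4\}$. The drug
  effect is linear rather than saturating so that concentration spikes
  are as myelotoxic as they are tumoricidal — with a saturating effect
  the optimizer exploits arbitrarily large boluses and the optimum
  degenerates to the dose bounds. The administration route follows the
  IV-bolus convention of the scenario's record table.
* **Biomarker indirect response** (days): turnover model with inhibition
  of production, elevated baseline $k_{in}/k_{out} = 20$, healthy target
  $B_{tar} = 10$ (reached at 50% sustained inhibition). Daily IV bolus
  for 42 days with weekly dose changes ($m = 6$); minimize the drug AUC
  subject to $B \le 10$ on $[14, 42]$, start 6 per group, schedule
  $\{1, 10^2, 10^4, 10^6\}$.
* **Antibiotic with adaptive resistance** (hours): two-compartment PK,
  1 h infusions at 0 and 12 h (same dose, $m = 1$), logistic bacterial
  growth with Emax kill whose EC50 inflates by $(1 + \beta \cdot AR)$
  through an exposure-driven adaptation state. Minimize the drug AUC
  subject to the mean count over $[6, 24]$ h staying $\le 100$. Growth
  and adaptation rates were set so that the mean-count constraint is
  *active* at an interior optimum of both the dose task and the
  fixed-dose (50 mg/kg) interval task — with slower regrowth the interval
  problem degenerates to its bound.

Passing tests on these problems demonstrate the *method*: constraint
activity at the optimum, the continuation pattern (margins approaching
their thresholds monotonically, $PFV/\rho \to 0$, doses converging
numerically), independence of $\rho$ and of the starting dose where the
problem is well-posed, and solver/oracle agreement. They do **not**
validate any drug-specific quantitative claim: the parameter values are
not estimates for real compounds, there is no inter-individual
variability, no parameter uncertainty, and real myelosuppression or
resistance dynamics are richer than these structures. The analytic toy
problems carry the exact-value burden instead: a one-compartment model
with closed-form solution yields a point-constrained problem whose
optimum $D^* = c\,V e^{k_e t_f}$ and multiplier
$\mu = (1 - e^{-k_e T}) e^{k_e t_f} / k_e$ are known, an interval problem
with trough-bound optimum
$\theta^* = T + \log(c_{max} V / A - e^{-k_e T}) / k_e$, and synthetic
trajectories (constants, ramps, curves with prescribed threshold
crossings) generate every penalty-calculus check from closed forms.

## Numerical choices and degenerate inputs

Dose bounds are enforced by the optimizer's box handling, never by
clipping inside the event expansion — out-of-bounds doses there are a
hard error, so a misconfigured caller cannot silently optimize a clipped
problem. Interval mode flags (but allows) schedules that collapse two
administrations onto the same time, and rejects schedules whose infusion
would extend beyond the horizon. Path constraints whose active region
shrinks to a window endpoint converge more slowly in $\rho$ (the
violation measure concentrates on a vanishing set); the corresponding
toy test runs at $\rho = 10^7$ where the point-constrained variant needs
only $10^5$. Ties in the grid oracle resolve to the first minimum;
refinement only ever replaces it by a strictly better point.

## Limitations

Penalty iterates are slightly infeasible at any finite $\rho$ (the
optimum sits where the marginal cost balances $\rho$ times the marginal
violation); users requiring hard feasibility should take the last
continuation stage's doses and verify margins via
`feasibility_report()`. No exact (interior-point/SQP) treatment of the
discretized state-constrained problem is provided, no global optimality
is claimed, doses and intervals cannot be optimized simultaneously, and
steady-state records, ADDL expansion and multi-subject data files are out
of scope. Sensitivity of the optimal doses to $\theta$ is not computed.
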