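---
title: "Expected utility, motor noise and the speed-accuracy trade-off in simulated arm reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected utility, motor noise and the speed-accuracy trade-off in simulated arm reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`reachsim` simulates goal-directed reaching with a two-joint, six-muscle
planar arm and asks a single question: if the nervous system chooses motor
commands to maximize the *expected* utility of a movement — the
probability-weighted average, over many noisy repetitions, of a temporally
discounted reward minus the muscular effort spent — do the classic
regularities of human reaching follow? Two trade-offs are in play at once.
The cost-benefit trade-off: a reward reached later is worth less
(discounting with time constant $\gamma$), but moving faster costs more
effort. The speed-accuracy trade-off: motor noise is signal-dependent, so
faster (stronger) commands are noisier, endpoint dispersion grows, and the
probability of actually collecting the reward falls. Maximizing

$$J(u) \;=\; \mathbb{E}\!\left[\, e^{-\mathrm{MT}/\gamma}\,\rho\,[\text{hit}]
\;-\; \upsilon \int \lVert u_t \rVert^2 \, dt \;-\; C(s_f) \right]$$

couples the two: the optimum movement time shifts later for smaller targets,
which is Fitts' law.

The expectation cannot be computed in closed form for a nonlinear noisy
plant, so the package estimates it by Monte-Carlo rollouts and optimizes the
controller parameters directly with CMA-ES, a derivative-free evolution
strategy suited to noisy black-box objectives.

### Plant

The arm is a standard planar double pendulum in the horizontal plane
(gravity absent), with rigid-body dynamics
$\ddot q = M(q)^{-1}(\tau - C(q,\dot q) - B\dot q)$. The inertia matrix
depends on the elbow angle only; the Coriolis vector is the usual
two-link closed form; $B$ is a small symmetric damping matrix lumping
unmodelled dissipation. Six muscles (shoulder flexor/extensor, elbow
flexor/extensor, and a biarticular pair) act through a constant moment-arm
matrix $A$: $\tau = A^\top (f_{\max} \odot \tilde u)$. The commanded
activation $u \in [0,1]^6$ is corrupted multiplicatively at every step,
$\tilde u = \mathrm{clamp}(u(1 + \kappa z),\,0,\,1)$ with $z$ a standard
normal draw per muscle — signal-dependent noise: silent muscles are
noiseless, strong commands are noisy. Defaults are standard literature
values for a human arm (masses 1.4/1.1 kg, lengths 0.30/0.35 m,
$\kappa = 0.3$, $\delta t = 2$ ms).

Numerical choices worth stating:

* **Integration** is semi-implicit Euler (velocity first, then position
  with the updated velocity). A plain explicit step is equally compatible
  with everything downstream; the semi-implicit variant is stable at the
  2 ms control step and conserves the passive arm's kinetic energy to
  better than $10^{-4}$ relative over 0.1 s at $dt = 10^{-5}$ s (an
  oracle test in the suite).
* **Joint limits** (shoulder $[-0.6, 2.6]$ rad from the $+x$ axis, elbow
  $[-0.2, 3.0]$ rad) are enforced by clamping the violating coordinate and
  zeroing its velocity. The convention places the shoulder at the origin
  so the target sits straight ahead at $(0, 0.6175)$ m — 95 % of full arm
  length.
* **Noisy activations are clamped** to $[0,1]$ after the noise is applied:
  the action space is declared a box, and the multiplicative formula alone
  can exit it.

### Task

The target is an interval of width $W \in \{5, 10, 20, 40\}$ mm centred at
$x = 0$ on the wall line $y = 0.6175$ m. Movements start at rest from 15
points on three arcs centred on the target at 15 %, 37.5 % and 60 % of arm
length (3, 5 and 7 points, spread over $\pm 45^\circ$ about the
target-to-shoulder axis). A movement ends when the end effector crosses the
wall line — the crossing point, found by linear interpolation inside the
crossing step, decides hit versus miss — or after a 4 s timeout. The
timeout is this package's choice (the task is formulated over an infinite
horizon); timed-out movements collect no reward and keep their full effort
cost.

The utility of one movement is
$J = [\text{hit}]\,\rho\, e^{-\mathrm{MT}/\gamma} - \upsilon \sum_t \lVert
u_t \rVert^2 \delta t - w_\perp v_x^2$, with $\rho = 3000$, $\upsilon = 1$,
$\gamma = 0.6$ s. Three points of interpretation:

* The reward integrand collapses to a terminal term because simulation
  stops at the wall; discounting therefore applies to the movement time.
* Effort is **not** discounted, and is computed from the commanded
  (pre-noise) activations.
* $C(s_f) = w_\perp v_x^2$ penalizes the tangential (along-wall) component
  of the end-effector velocity at crossing, favouring perpendicular hits.
  The squared form keeps the penalty sign-symmetric. The weight
  $w_\perp = 1$ was fixed once so that the penalty is of the same order as
  the other non-reward terms on pilot rollouts; it is a configuration
  parameter, not a fitted quantity.

### State estimation

The controller never sees the true state. Sensory feedback arrives
$\Delta = 10$ steps (20 ms) late; the applied command differs from the
efference copy by the motor noise. The estimator maintains two terms: an
open-loop prediction that integrates the noise-free forward model from its
own previous output, and a closed-loop term that takes the delayed true
state and rolls it forward through the $\Delta$ buffered efference copies.
The estimate is their weighted average with $k_1 = 0.2$, $k_2 = 1.0$.
Sensory noise is deliberately absent, which is what makes this simpler
than a Kalman filter: the delayed state is exact, so the closed-loop term
can only accumulate the noise of the last $\Delta$ steps, and it re-anchors
the estimate whenever the arm slows. During the first $\Delta$ steps no
delayed measurement exists; the closed-loop term rolls the (exactly known)
initial state forward through the commands issued so far. The open-loop
term evolves independently for the whole movement — it is never re-anchored
to the combined estimate.

### Controller and optimization

One feed-forward network per starting point maps the 4-D state estimate to
six activations: 4 inputs, $N_h = 10$ tanh hidden units, 6 logistic
outputs (116 parameters). Logistic outputs guarantee the $[0,1]^6$ action
box without clipping. Activation functions and input scaling are this
package's choices (the network architecture itself is fixed): joint angles
are mapped affinely to $[-1,1]$ by the joint limits and velocities divided
by 20 rad/s, keeping the units in their sensitive range, and making stored
policies transferable between runs. Parameters are initialized uniformly
in $[0, 0.1]$.

CMA-ES maximizes the Monte-Carlo expected utility, with each candidate
evaluated on `repet` fresh rollouts. The study budget is popsize 30,
up to 5000 iterations, `repet` 50. Three design points:

* Candidate rollout streams are derived from (master seed, iteration,
  candidate index) with a counter-based hash, so runs are bit-reproducible
  and the stream of a candidate does not depend on the population size.
* Candidates are ranked by their single-iteration mean; no averaging
  across iterations, no common random numbers (independent seeding keeps
  the Monte-Carlo estimator unbiased). The returned controller is the best
  candidate ever *evaluated*, which makes the best-so-far trace monotone
  by construction — at small `repet` this choice is optimistically biased
  by evaluation noise, which is the main reason small smoke budgets
  produce noticeably weaker controllers than the study budget.
* Each (target width, start point) pair is optimized independently — 60
  optimizations for the full campaign — because the per-width dependence
  of the behavioural readouts requires width-specific controllers.

## What the analysis computes

* **Fitts regression**: mean movement time per (distance, width) cell
  against $ID = \log_2(D/W)$, by ordinary least squares (3 distances x 4
  widths = 12 points). Cell means use all wall-crossing movements, hits
  and misses alike; restricting to hits is a switch (`hits_only`), since
  the convention is not decidable from the reaching literature alone.
* **Hit dispersion**: crossing x-coordinates binned at 0.5 mm around the
  target centre; a Gaussian is fitted to the bin counts by least squares
  (maximum likelihood on the raw hits is available as `method = "ml"`).
  Reported: $\mu$, $\sigma$, hit rate, and the peak offset as a
  percentage of target width.
* **KL divergence** between fitted dispersion Gaussians, in closed form,
  direction fixed as KL(model ‖ reference); the closed form is tested
  against quadrature.
* **Velocity profiles**: end-effector speed via the kinematic Jacobian;
  peak speed, time of peak, terminal speed, and the asymmetry ratio
  time-of-peak / MT (flat profiles report 0.5 by convention).
* **Normalized tables**: 3 x 4 cell means of peak speed and movement time,
  normalized to the (short distance, 5 mm) cell.

## Scaled problem sizes, and what they do and do not show

All data in this package are simulated by the package itself; the
synthetic campaign *is* the study. The full campaign — 60 CMA-ES runs at
popsize 30 x 5000 iterations x 50 rollouts per candidate, i.e. about
7.5 million rollouts per controller — is a multi-day single-CPU
computation. The test suite and the acceptance script therefore run the
same pipeline at reduced scale, chosen once:

* smoke checks: 2 widths x 3 starts, popsize 8, 50 iterations, 6 rollouts
  per candidate;
* quantitative readouts: 4 widths x 3 starts (the middle point of each
  arc), popsize 16, 300 iterations, 12 rollouts per candidate, 100
  evaluation rollouts per controller.

Reduced budgets change what converges. Robust at desk scale: optimization
improves on the initial controller; peak speed grows with start distance;
movement time grows with distance; dispersion and hit rate respond to
target width. Emerging but fragile at desk scale: the movement-time
ordering across widths (the Fitts slope), because it requires the
small-target controllers to discover that slowing down buys hit
probability — a reward signal that is nearly silent while hit rates are
still low. Not reached at desk scale: strongly asymmetric bell-shaped
velocity profiles with an early peak. Those require controllers that brake
before the wall, which the full budget finds and reduced budgets do not;
at desk scale the velocity peak sits at the crossing. The package reports
these readouts as computed and makes no claim that desk-scale budgets
reproduce the full-budget endpoints.

Two further idealizations relative to real reaching data: movements start
exactly at each start-point centre (no within-start variability), and
there is no sensory noise, no muscular friction, and no external damping
of the kind a haptic manipulator adds — so absolute movement times are
faster than human ones, and comparisons are made on normalized quantities.

## Degenerate inputs and edge conventions

* $\kappa = 0$ makes the whole loop deterministic: the estimator is exact,
  repeated rollouts are identical, and the expected utility equals the
  single-rollout utility (tested).
* A silent controller never crosses the wall: outcome `timeout`, reward 0.
* Dispersion fitting falls back to moment estimates when the
  histogram least-squares fit cannot proceed (fewer than 10 crossings, or
  a degenerate single-bin histogram).
* Fitts fitting refuses single-ID designs; normalized tables name the
  first empty cell they encounter.
* Unreachable start or target points are rejected with the offending
  radius.

## Known limitations

* CMA-ES is implemented in plain R (no package in the dependency set
  provides it); it follows the standard reference formulation and is
  validated on analytic benchmarks, but implements no restarts, no
  noise-adaptive re-evaluation, and no early stopping — by design, since
  the study protocol stops on iteration count alone.
* The closed-loop estimator term costs $\Delta$ forward-model evaluations
  per control step. The rollout loop is compiled (C++) for this reason; a
  learned one-call approximation of the $\Delta$-step roll-forward exists
  as an optimization in the literature but is intentionally not used here
  — the exact iteration is the reference computation.
* Hit/miss is decided in R after the compiled rollout returns the crossing
  coordinate, so one simulation could in principle be scored against many
  widths; the campaign driver nevertheless re-optimizes per width, as the
  study design requires.
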