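---
title: "A predictive-control model of rat stance on a tilting floor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A predictive-control model of rat stance on a tilting floor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being modelled

A rat standing bipedally on a platform receives a light cue; about 0.9 s
later the platform rotates backward (toes-up) by 8.8 degrees over 0.25 s.
After repeated trials the animal's postural response to the tilt shrinks
markedly: it has associated the cue with the upcoming disturbance and
controls its posture predictively. `ratstance` implements a mathematical
account of that behaviour and everything needed to exercise it on synthetic
data: the body model, the controllers, parameter identification from
centre-of-mass (CoM) angle traces, and the marker-based kinematics used to
quantify which body segments drive the CoM response.

## Body model

The body is reduced to a single inverted pendulum from the
metatarsophalangeal (MTP) joint to the whole-body CoM, with backward
rotation positive:

$$ J\ddot\theta = mgh\sin\theta + \tau + \tau_{Floor} + \sigma\xi, \qquad
   \tau_{Floor} = -k_P(\theta - \phi) - k_D(\dot\theta - \dot\phi), $$

where $\phi(t)$ is the floor angle, $\tau$ the active control torque,
$\sigma\xi$ additive Gaussian torque noise, and $k_P$, $k_D$ the passive
elastic and viscous coefficients of the tissues crossing the MTP joint.
When the floor is level the passive torque stabilizes; during a tilt it
drags the body along with the floor and acts as the disturbance. Body
constants default to the measured averages $m = 0.404$ kg, $h = 0.107$ m.
The moment of inertia is not measurable from the marker set; we take
$J = mh^2$ (all mass at the CoM), consistent with the single-link
reduction, and expose it for override. Stiffness-like gains are expressed
as dimensionless multiples of $mgh \approx 0.424$ N·m throughout.

Simulation uses a fixed 1 ms step matching the controller rate. Within a
step the deterministic drift is integrated with a classical Runge–Kutta
scheme while the control and noise torques are held constant; the noise
torque is redrawn each step. A plain Euler stepper is available
(`sim_config(integrator = "euler")`), but its per-window error against a
tight adaptive reference integration is on the order of $10^{-3}$ rad,
whereas the default stepper agrees to better than $10^{-8}$ rad, so the
higher-order stepper is the default. The noise magnitude `sigma` is by
default the per-sample standard deviation at 1 kHz (the identified value,
0.50 mNm, is plausible on that reading against $mgh$); a
$\sigma/\sqrt{dt}$ continuous-intensity scaling is available as a config
switch because the discrete scaling convention is genuinely ambiguous.

## The predictive controller

The trained animal is modelled by receding-horizon control with disturbance
preview. At every step the controller forecasts the body angle over the
prediction horizon $H_p$ using a linear internal model — the
zero-order-hold discretization of the linearized plant above, assumed to be
an exact copy acquired by learning — and chooses the input sequence
minimizing the sum of squared predicted angles (the target angle is always
zero). The planned input may vary over the first $H_u$ steps (the control
horizon) and is then held constant (move blocking); only the first move is
applied. Because there are no inequality constraints the whole law
collapses into precomputed linear gains over the current state estimate,
the previous input and the floor-angle preview (`mpc_gain()`), making
closed-loop simulation cheap enough for population-based identification.

Three cost weights matter:

* `state_weight` (default 1) on the squared predicted angle;
* `input_move_regularizer` (default 0.1) on squared input increments. This
  is not a mere conditioning term: with a vanishing increment weight the
  unconstrained preview law cancels the tilt to numerical zero
  ($\sim 10^{-5}$ rad), far below the torque-noise floor, leaving nothing
  for identification to grasp. The default mirrors the conventional
  output-weight-1 / input-rate-weight-0.1 choice of the industrial MPC
  toolboxes this controller family emulates, and produces responses on the
  degree scale observed in animals;
* `input_weight` (default 0) on input amplitude, exposed for exploring
  weaker-authority controllers.

Sensory delay (default 40 ms) enters as a measurement delay. By default the
controller forward-predicts the stale measurement through its internal
model using the stored inputs and observed floor history
(`delay_compensate()`, a standard predictor structure); acting on the stale
measurement directly is available via
`mpc_config(delay_compensation = FALSE)`, but with the default weights that
loop is unstable at the identified operating point.

With the identified parameters the model shows a distinctive anticipatory
pattern: once the upcoming tilt enters the preview window the optimizer
begins torquing and leans the body slightly *before* tilt onset — the
input-increment cost makes a gradual early adjustment cheaper than a fast
late one, and move blocking forces each plan to commit to a near-constant
input across the ramp. The post-onset excursion proper is then small. Two
conventional reactive baselines are provided for contrast: a linear PD
controller with classic human quiet-stance gains
($k_P = 1.46\,mgh$, $k_D = 0.3\,mgh$) and a nonlinear PD controller with
gains reported for quiet standing rats
($k_{P2} = 196\,mgh$ on $\theta\lvert\theta\rvert$, $k_{P0} = 0.88\,mgh$,
$k_D = 0.11\,mgh$; the quadratic term is implemented with odd symmetry
because its sign for backward-negative angles is otherwise ambiguous).
Both act on the delayed measurement without an internal model.

Two known divergences from the reference behaviour this model family is
meant to echo, both consequences of exact predictor compensation, are
documented rather than hidden: (i) across a prediction-horizon sweep the
peak CoM angle *grows* with $H_p$ here (short-horizon controllers track
tightly on compensated feedback; long horizons pre-lean), whereas the
reference behaviour has both peak CoM and peak torque falling as $H_p$
grows — the post-onset peak torque does fall monotonically here; (ii) a
preview-deprived copy of the trained controller tracks the ramp almost
perfectly on feedback alone, so it cannot serve as a surrogate for a naive
animal; the naive surrogate defaults to the PD baseline instead.

## Parameter identification

Five parameters are free: $H_p$, $H_u$, $k_P$, $k_D$, $\sigma$. Given a
target CoM-angle trace over $[-0.35, 0.45]$ s around tilt onset, the
objective simulates five noise replicates at a candidate, averages the
angle traces sample-wise, and returns the mean squared error against the
target; unstable candidates receive a large finite penalty ($10^6$ rad²).
Search bounds default to $H_p \in [0.03, 1.3]$ s, $H_u \in [2, 50]$ ms,
$k_P \in [0, 1.5]\,mgh$, $k_D \in [0, 0.3]\,mgh$,
$\sigma \in [0, 2]$ mNm.

The search is a genetic algorithm (population 40, tournament selection,
blend crossover, Gaussian mutation annealed from 10% of each range,
elitism 2) followed by a local refinement stage: Nelder–Mead polish of the
top elites under common random numbers, alternated with line searches over
both horizons at the 1 ms step resolution. The refinement stage exists
because the objective is a rippled staircase along the horizons (they round
to whole steps, and the blocked input interacts with the ramp), with
well-separated local minima — e.g. an $H_u$-at-the-bound valley whose
objective is within two orders of magnitude of the true minimum. Plain GA
populations collapse into such valleys; the line searches reliably step out
of them. All evaluation seeds derive deterministically from the run seed,
so identification is exactly reproducible.

One parameter deserves a caveat: because the objective averages the
replicate traces, the noise magnitude $\sigma$ enters expectation only
through a variance penalty $\propto \sigma^2/5$ that is *minimized at
zero*, plus a chance-alignment term between the candidate's realized noise
and the target's. $\sigma$ is therefore weakly identified and biased low
under this (faithful) objective; recovered values scatter broadly over the
lower half of the bounds. The other four parameters are sharply identified:
perturbing any of them by one reported spread raises the objective three to
five orders of magnitude above its floor.

## Segment kinematics

The marker side analyses sagittal coordinates of nine landmarks (MTP,
lateral malleolus, knee, greater trochanter, iliac crest, scapula, the
iliac-crest–scapula midpoint, temporomandibular joint, nose) at 200 Hz,
smoothed with a zero-phase 4th-order Butterworth low-pass at 15 Hz
(zero-phase filtering is the package's choice; only the filter family and
order are dictated, and phase-free smoothing is standard for kinematics).
A five-segment rigid-link model (foot, leg, lower trunk, upper trunk,
head) carries measured inertial fractions: masses 1/9/53/29/8% of body
mass, CoM positions $L_s$ = 32/68/18/40/33% along the segment line and
$L_v$ = 0/0/33/10/−7% perpendicular to it. Positive $L_v$ is taken to
displace the segment CoM ventrally (the head's negative value then points
dorsally); the source convention is not fully specified, so fixtures pin
down this package's convention rather than the original's.

The per-segment contribution of rotation to the CoM angle is

$$ E_i = \int_0^{0.3} \frac{m_i}{M}\,
   \frac{\mathbf r\cdot\mathbf r_i}{\lvert\mathbf r\rvert\,
   \lvert\mathbf r_i\rvert}\;\omega_i\,dt, $$

with $m_i$ the mass of the body part from segment $i$ upward, $\mathbf r$
the MTP-to-CoM vector, $\mathbf r_i$ the vector from segment $i$'s lower
marker to the CoM of the body part above it, and $\omega_i$ the segment's
angular velocity (central differences on unwrapped angles; trapezoidal
integration; signed normalized dot product). The statistic presumes the
body above the segment of interest rotates rigidly about the segment's
lower end. For $\omega_i$ the package defaults to the segment's rotation
*relative to the segment below* (joint angular velocity; the foot rotates
relative to the ground): under that reading the per-segment effects of a
chain motion add up to the CoM-angle change whenever the rigid-above-joint
picture holds — exactly so for whole-body rotation about the MTP, and to
within a few percent for foot-dominated multi-joint motions, the error
being the $\lvert\mathbf r\rvert/\lvert\mathbf r_i\rvert$ factor by which
the normalized dot product deviates from the exact lever ratio. The
absolute-velocity reading (`omega = "segment"`) is also provided; its
per-segment values overcount when several joints move at once.

## Synthetic data

Because the original recordings are not deposited, the generator stands in
for them, with defaults equal to the identified operating point
($H_p = 0.96$ s, $H_u = 24.4$ ms, $k_P = 0.34\,mgh$, $k_D = 0.03\,mgh$,
$\sigma = 0.50$ mNm) under the experimental constants (8.8°/0.25 s ramp,
1 ms sampling, 40 ms delay, window $-0.35$ to $0.45$ s, body at rest at the
window start), 18 sequences by default with per-sequence derived seeds.
What the generator emulates: the closed-loop trace statistics of the model
itself — which is precisely what self-consistent identification tests
need. What it does not emulate: multi-segment compliance, foot lift-off,
measurement/tracking error in the markers, or any across-trial learning
dynamics. Passing recovery tests therefore demonstrates that the pipeline
identifies the model from model-generated data at realistic noise levels,
not that the model family is correct for real rats. The marker-motion
generator (`synth_marker_motion()`) builds the nine-landmark chain forward
from prescribed segment-angle functions, so segment angles and angular
velocities are known exactly by construction.

## Numerical choices and degenerate inputs

* Horizons in seconds are rounded to whole steps, minimum one; $H_u$ is
  clipped to $H_p$; the sensory delay must be a whole number of steps.
* The stacked least-squares problem behind the preview gains is solved by
  pivoted QR; degenerate weightings surface as a rank-deficiency error.
* A trajectory whose angle passes $\pm\pi/2$ counts as fallen
  (`is_stable()`); the simulator freezes a trace at $\pm 10$ rad to avoid
  overflow and flags it, and a controller emitting a non-finite torque
  aborts with the offending step.
* Ramp corners land exactly on sample boundaries; floor-rate evaluation
  carries a $10^{-12}$ s tolerance and integrator stages stay strictly
  inside their step so corner samples classify consistently.
* Identification targets snap their recovered sampling interval to 9
  decimals so that a file round-trip cannot flip corner classification.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full identification window
at 1 ms resolution. Recovery studies use five synthetic sequences;
GA budgets are population 40 with up to 30–60 generations in the
acceptance script and a reduced population of 24 with 15 generations in
the test suite — the local refinement stage, not the GA budget, sets the
final precision. Sweep and stability experiments use 10 seeds per setting;
sweep properties in the tests use single-seed-per-sequence designs over 18
sequences. These sizes are the package's chosen defaults for a desk-scale
reproduction; all are configurable upward.

## Known limitations

* The controller family is a clean-room receding-horizon law; the exact
  weighting, estimator and preview semantics of any particular commercial
  toolbox are not replicated, and quantities that depend on those internals
  (notably the exact location of the short-horizon stability boundary, and
  the direction of the peak-CoM trend across prediction horizons) can land
  elsewhere than reported for such toolboxes.
* $\sigma$ is weakly identified by the averaged-trace MSE objective (see
  above); treat recovered noise magnitudes as order-of-magnitude only.
* The single-link reduction ignores inter-segment dynamics by design; the
  kinematics module quantifies, but the dynamic model does not use,
  multi-segment structure.
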