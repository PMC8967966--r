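---
title: "Closed-loop elbow-exosuit simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop elbow-exosuit simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system being simulated

`exoflex` simulates a planar human elbow driven by six Hill-type muscles
(biceps long and short heads, brachialis; triceps long, medial and lateral
heads) while a soft cable-driven exosuit assists flexion.  The shoulder is
locked with the upper arm vertical, so the only degree of freedom is the
elbow flexion angle $\theta$, measured from the downward vertical
($\theta = 0$ arm hanging, $\theta = \pi/2$ forearm horizontal).  The task is
a point-to-point flexion from 0 to 90 degrees along a minimum-jerk
trajectory, completed in 1 s (fast) or 2 s (slow), with a hand-held mass of
0, 2 or 5 kg.

Each control step of the closed loop performs, in order:

1. **Feedback read.** The measured $(\theta, \dot\theta)$ comes from the
   forward model at the current grid point.
2. **Assist controller.** When the actuator is ON, the gravity-compensation
   (GC) law demands $\tau_a = (m g l_c + M g l_l)\sin\theta$ using only the
   measured angle — the flexion moment gravity would otherwise require.
3. **Inverse dynamics with PD feedback.** The commanded acceleration is
   $\ddot\theta = \ddot\theta_{des} + k_p(\theta_{des}-\theta) +
   k_v(\dot\theta_{des}-\dot\theta)$ and the net muscle moment
   $\tau = I\ddot\theta + G(\theta) - \tau_a$.  The centripetal/Coriolis term
   is identically zero for a single revolute joint.
4. **Static optimization.** Muscle redundancy is resolved by minimizing
   $\sum_i a_i^2$ subject to $\tau = \sum_i d_i F_i(a_i)$ and
   $0 \le a_i \le 1$.
5. **Excitation computation.** The backward-difference rate of the optimizer
   targets is inverted through the activation dynamics to produce the
   excitations $u_i$ sent to the plant.
6. **Forward dynamics.** The joint state and the six activation states are
   integrated to the next grid point with excitations and cable tensions
   held (zero-order hold).

The pipeline is deterministic end to end: re-running a specification
reproduces the result bit for bit, and permuting sweep order leaves every
cell unchanged.

# Models and their parameters

## Rigid dynamics

The forearm plus load rotate about the elbow with inertia
$I = I_{zz} + M l_l^2$.  The tabulated forearm inertia
($I_{zz} = 0.02\,$kg m$^2$, declared *about the elbow joint*) is used as
given; because its magnitude is comparable to $m l_c^2 = 0.0496$ kg m$^2$,
the alternative reading (a COM value, to which $m l_c^2$ must be added) is
selectable via `inertia_frame = "com"`.  This choice scales the inertial
torque and is the single most influential ambiguity in the source
parameter set.

Defaults (SI units): forearm mass 1.53 kg, COM distance 0.18 m, load
distance 0.35 m, gravity 9.81 m/s$^2$, gains $k_p = 900$ s$^{-2}$ and
$k_v = 60$ s$^{-1}$.  All are configuration fields; in particular the
elbow-to-load distance depends on where the mass is held in the hand and is
worth varying (0.29 m is an equally plausible value for this task).

## Muscle model

Force follows the Hill form
$F = F_m\,[f(l)\,f(v)\,a + f_p(l)]\cos\phi$ with Thelen-family curve
constants: active force-length Gaussian width $\gamma = 0.45$; passive
exponential with shape $k = 4$ and strain 0.6 at maximal force, clamped to
zero below slack length; force-velocity with Hill shape $A_f = 0.25$
(zero force at maximal shortening) and eccentric plateau 1.4 with a
slope-continuous junction at zero velocity.  The force is linear in
activation — $f(v)$ is evaluated as a pure velocity curve — which keeps the
forward plant exactly consistent with the linear moment equality that static
optimization enforces.  Activation dynamics use
$\dot a = (u - a)/\kappa(a, u)$ with
$\kappa = \kappa_{act}(0.5 + 1.5a)$ when activating and
$\kappa_{deact}/(0.5 + 1.5a)$ when deactivating;
$\kappa_{act} = 0.010$ s and $\kappa_{deact} = 0.040$ s.

A rigid tendon with a constant-thickness pennation model
($l \sin\phi = l_{opt}\sin\phi_{opt}$) keeps fiber length and velocity
algebraic in the joint state, which in turn keeps the per-step redundancy
problem a box-constrained quadratic program.  No elastic-tendon equilibrium
is solved; this is an accepted fidelity gap documented below.

## The packaged muscle fixture

Muscle-level parameters are not part of the task definition, so the package
ships a reconstruction based on the public arm26 musculoskeletal model
(`inst/extdata/arm26_muscles.yaml`, provenance comments in the file):

* architecture ($F_m$, $l_{opt}$, $l_{ts}$, pennation, time constants)
  transcribed from the publicly documented arm26 values;
* signed elbow moment arms as polynomials in $\theta$ (degree $\le 2$,
  valid on $[-0.1, 1.8]$ rad), matched to published elbow moment-arm
  measurements: biceps peaking near 4.5 cm around 80–100° of flexion,
  brachialis near 2.7 cm, triceps near 2.0–2.5 cm and weakly
  angle-dependent;
* MTU-length polynomials taken as the *exact* antiderivatives of the
  moment arms, so $dL/d\theta = -\mathrm{sign}\cdot|d(\theta)|$ holds
  identically (a property the tests verify numerically);
* integration constants that place flexor fibers at optimal length at
  $\theta = 0.8$ rad and extensor fibers at $\theta = 1.2$ rad, matching
  the published operating ranges of the arm26 elbow muscles (flexors
  slightly stretched at full extension, triceps slightly stretched at full
  flexion).

These choices were fixed from the public model descriptions, not adjusted
against outputs.  One consequence worth knowing: at full extension the
flexors sit at $\tilde l \approx 1.18$, so their passive forces
(tens of newtons) are non-negligible.  They supply a passive flexion moment
near $\theta = 0$ that the triceps must cancel — the simulation therefore
shows a small unassisted triceps baseline — and they dominate the elbow
reaction force in the unloaded condition.

Effective straight-line origin/insertion points per muscle (also in the
fixture) orient the muscle force vectors for the reaction-force balance
only; they do not participate in the moment computation.

## Static optimization

The per-instant problem — minimize $\sum a_i^2$ subject to one linear
moment equality and box bounds — has a separable quadratic objective, so its
KKT conditions reduce to $a_i = \mathrm{clip}(\mu c_i, 0, 1)$ for a scalar
multiplier $\mu$, with $c_i = d_i \times$ (active moment capacity).  The
delivered moment is continuous and nondecreasing in $\mu$, and the solver
finds the exact solution by a monotone root solve (bracketing plus
`uniroot` at machine tolerance).  This replaces a generic interior-point
iteration with the problem's closed-form structure; tests verify it against
an independent projected-KKT derivation, a brute-force grid search, and a
continuity property.  The activation lower bound is exactly zero: the small
positive baseline a generic interior-point solver would leave on inactive
muscles is treated as a numerical artifact and *not* modeled.

When the demand exceeds total muscle capacity, an optional reserve actuator
(default ON) supplies the residual moment under a quadratic penalty of
weight 1000, and the residual is recorded in the run diagnostics.

## Exosuit

One anchor pair (upper arm: 4 cm anterior, 14 cm above the elbow; forearm:
2 cm offset, 15 cm along the forearm) serves both cables; the flexor cable
routes anteriorly and the extensor cable mirrors it posteriorly.  Cables are
straight segments except that a segment passing within the wrap radius
(default 2.5 cm, configurable) of the joint wraps a cylinder around it: the
cable then leaves its anchor tangent to the cylinder, its moment arm equals
the wrap radius and its pull direction is the tangent direction.  Without
this, the posterior cable's straight line crosses the elbow near
$\theta = 0.45$ rad and its moment arm would change sign, which is
geometrically and physically wrong for a cable routed over the olecranon.

A positive assist moment is carried entirely by the flexor cable
($T_1 = \tau_a/r_1$), a negative one by the extensor cable; at most one
cable is ever taut.  Strap interaction forces are the cable force at the
forearm anchor decomposed along (shear) and perpendicular to (normal) the
forearm axis.  Because the GC law depends on $\theta$ only, these forces
are functions of the joint angle alone — slow and fast tasks produce the
same force at the same angle.

## Metabolic model

Per-muscle energetic rates follow the Umberger-family parameterization:
muscle mass $\rho F_m l_{opt}/\sigma$ ($\rho = 1059.7$ kg/m$^3$,
$\sigma = 0.25$ MPa); activation-plus-maintenance heat
$(128\,\mathrm{FT} + 25)$ W/kg scaled by $A^{0.6}$ with
$A = u$ if $u > a$, else $(u+a)/2$, the 60% maintenance share additionally
scaled by the force-length curve above optimal length; shortening heat with
slow/fast-twitch coefficients $100/\bar v_{ST}$ and $153/\bar v_{FT}$ and
$A^2$ dependence; lengthening heat with coefficient $4\times$ the
slow-twitch value and first-power $A$; an aerobic scale of 1.5 and a
1 W/kg lower bound on total heat, absorbed into the maintenance term.
Mechanical work rate is $-F v$ per fiber, clamped at zero during
lengthening by default (`allow_negative_work` retains absorbed work).  The
basal rate is 1.2 W per kg of modeled muscle mass.  The reported scalar per
run is the RMS of the total rate over the task window.  Fast-twitch
fractions default to 0.50 (flexors) and 0.55 (extensors).

The bookkeeping identity
$\dot E = \dot B + \dot A + \dot M + \dot S + \dot W$ holds exactly at
every sample by construction and is asserted in the tests.

# Numerical choices

* **Grid.** 121 Hz sampling, inclusive of both endpoints: 121 samples for
  the 1 s task, 241 for the 2 s task.  Controls are held between grid
  points.
* **Integrator.** Adaptive Dormand–Prince (deSolve `ode45`) with
  `rtol = 1e-6`, `atol = 1e-8`, maximum step 0.02 s; robustness across the
  0.004–0.02 s step-bound range is a tested property (RMS joint moment
  changes < 2%).
* **Startup.** $\theta(0) = \theta_{ref}(0)$, $\dot\theta(0) = 0$, and the
  initial activations are set to the static-optimization solution of the
  $t = 0$ demand, avoiding an artificial startup transient.  The
  target-activation rate at $t = 0$ is zero.
* **Degenerate inputs.** Angles outside the polynomial fit range are
  clamped (flagged on the state); fiber projections are floored at 1 µm;
  the simulation aborts with diagnostics if $\theta$ leaves
  $[-0.2, 2.0]$ rad or the integrator returns a non-finite state.
* **Excitation inversion.** The branch of the activation time constant is
  determined by the sign of the demanded rate; results are clamped to
  $[0,1]$ and clamp events are counted in the run diagnostics.

# What the simulation does and does not emulate

The task generator defines the study conditions: minimum-jerk references
(the quintic $10s^3 - 15s^4 + 6s^5$), two speeds, three loads, assist
ON/OFF, 121 Hz.  The quintic implies peak velocities of
$1.875\,\Delta\theta/T$ and peak accelerations of about 9.1 rad/s$^2$
(fast) and 2.3 rad/s$^2$ (slow).

Passing tests show that the *closed loop* behaves as specified under this
reconstructed muscle set.  They do not show fidelity to any individual's
physiology: the muscle geometry is a polynomial stand-in for wrapped
OpenSim paths, the tendon is rigid, there is no joint-limit contact, no
passive joint structure, no Bowden-cable friction, no strap compliance, and
metabolic totals cover only the six modeled muscles.  Quantities that
depend on near-zero activation levels (percent reductions of already-small
activations, metabolic rates at rest) are sensitive to the exact-zero
activation floor discussed above and to the Umberger variant chosen; both
are documented switches.

# Problem sizes

The shipped analyses use the task's native sizes: single runs of 121 or
241 control steps with a 6-variable quadratic subproblem per step (about a
second per run), and the full 12-run factorial for the summary tables.
Property tests use the same sizes or smaller grids (41–61 samples) where
only loop mechanics are exercised; oracle comparisons (dense-Euler
activation traces, 40001-sample finite-difference grids, $11^5$-point grid
searches) are sized to keep the whole suite under a minute.
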