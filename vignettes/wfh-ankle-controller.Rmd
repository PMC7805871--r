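---
title: "A winding-filament muscle model as an adaptive ankle prosthesis controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A winding-filament muscle model as an adaptive ankle prosthesis controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfhankle)
```

## The problem

Powered ankle-foot prostheses replace the push-off work of the lost calf
musculature, but their torque controllers are typically state machines tuned
for one terrain: walking on stairs with a level-walking controller produces
too little plantarflexion, and switching control modes needs extra sensing
or user signals. Biological muscle, by contrast, adapts instantaneously to
changed loads because its stiffness is a function of its own length and
velocity — a "preflex" that needs no feedback loop.

`wfhankle` implements a torque controller built from that observation: two
virtual muscles whose force generation follows the winding filament
hypothesis (WFH) of muscle contraction pull on a hinge ankle. The
controller's only real-time input is the ankle angle stream plus a
five-state gait-stage label; the same parameter set serves level walking at
any speed and stair ascent.

## The muscle model

Each virtual muscle-tendon unit has four mechanical elements:

* a contractile element (CE) producing `Fce = act(t) * fl(Xm) * P0`, where
  `act` is the stage-dependent activation in [0, 1], `fl` the parabolic
  force-length factor (1 at the optimal length `L0`, zero at
  `L0 * (1 ± fl_width)`), and `P0` the peak isometric force;
* a viscous damper in parallel with the CE, a linear stand-in for the
  force-velocity relation, with separate constants for lengthening
  (`Cce_l`) and shortening (`Cce_s`);
* a linear titin spring (`kts`) that is wound onto the thin-filament pulley
  by CE activity, so its engagement — and hence the muscle's stiffness — is
  activation- and history-dependent;
* a linear series spring (`kss`, tendon and aponeurosis) attached at the
  pulley axle, whose deflection is the muscle's output force `Fss`.

The pulley is massless and frictionless, so both of its force balances hold
at every instant: the rotational balance `Fce + Cce*vce = kts*Xts` and the
translational balance `Fce + Cce*vce + kts*Xts = kss*(Xm - Xp)`.
Superposing the two balances gives the CE velocity

```
vce = (kts*Xts - Fce)/Cce + (kss*(Xm - Xp) - Fce - kts*Xts)/Cce
    = (kss*(Xm - Xp) - 2*Fce)/Cce ,
```

in which the titin terms cancel exactly (`ce_velocity()` implements the
two-term form; a property test asserts the cancellation).

### Closure of the pulley kinematics

The force balances alone do not determine how the titin elongation `Xts`
and pulley position `Xp` evolve; the published equations leave the winding
kinematics open. The package closes the system by imposing both balances at
all times, which yields the algebraic constraint `kss*(Xm - Xp) =
2*kts*Xts` (the pulley is quasi-static and the output force is always
`Fss = 2*kts*Xts`), and by differentiating that constraint together with
the no-slip winding relation `dXts = dXp - dXce`:

```
dXts/dt = kss * (dXm/dt - vce) / (kss + 2*kts),   Xts >= 0 (clipped).
```

This closure has the properties the model is meant to have, and the test
suite pins each one:

* **Isometric development.** A step of activation at constant length drives
  `Fss` monotonically to `2*Fce` (rotational equilibrium `kts*Xts = Fce`
  substituted into the translational balance), with first-order time
  constant `Cce*(kss + 2*kts) / (2*kts*kss)` — about 0.18 s for the
  posterior muscle while shortening, about 0.7 s for the anterior.
* **History dependence.** Stretching the active muscle pumps extra strain
  into the wound titin spring, which then relaxes through the damper: the
  force 1 s after a ramp-hold stretch is above the isometric force at the
  same final length, and strictly increasing in stretch amplitude; active
  shortening mirrors this below the reference (residual force enhancement
  and depression). Because the relaxation is exponential, the residual at
  the 1-s read-out is a few percent of the peak effect; the read-out time
  is a protocol parameter (`measure_offset`).
* **Passive behaviour.** With `act = 0` the rest state is an exact fixed
  point; passive stretch produces transient viscoelastic force (titin is
  engaged by pulley translation), and the net work of a passive muscle over
  a closed gait cycle is non-positive.

A state-update rule that instead re-solves the translational balance for
`Xp` with the damping term included, integrating `dXts = vce*dt - dXp`, was
evaluated first and found to be divergent (the pulley position ratchets
away by `Fce/kss` per step once titin clips at zero); the equilibrium
closure above replaces it. The update is isolated inside `advance_state()`
so an alternative closure can be swapped in.

### Integration

The state is advanced by explicit Euler at the controller rate of 500 Hz
(`dt = 1/500 s`), the rate at which the real controller runs; the damping
direction is chosen from the previous step's CE velocity (ties take the
lengthening constant, since the damper represents the CE's own
force-velocity relation). `oracle_advance()` provides a sub-stepped
reference with linearly interpolated inputs; over a level-walking stride
the 500 Hz Euler solution stays within 1% of `P0` of a 100x-refined
reference, and the deviation scales linearly with `dt` (first order).
Numerical-failure errors name the offending state variable and, from the
controller, the sample index and muscle.

## Ankle geometry and the controller

The skeleton is a hinge ankle between a shank and a foot segment; the ankle
angle `theta` is 0 with the foot perpendicular to the shank, positive in
dorsiflexion, negative in plantarflexion. Each muscle runs in a straight
line from its shank attachment (`SAL_A` = 29 cm, `SAL_P` = 33 cm above the
joint) to its foot attachment (`FMA_A` = 4 cm, `FMA_P` = 5.5 cm from the
joint). With included angles `gamma_A = 90° - theta` and `gamma_P = 90° +
theta`, the law of cosines gives the muscle lengths; plantarflexion
lengthens the anterior muscle and shortens the posterior one, strictly
reciprocally. The moment arm is the virtual-work arm `|dLm/dtheta| =
SAL*FMA*sin(gamma)/Lm`, which equals the perpendicular distance to the
muscle's line of action and is approximately the constant `FMA` near
`gamma = 90°`; a constant-arm mode is available as a configuration switch.
Whether the original controller used the geometric or the constant arm is
not documented; the geometric arm is the default here because it is the
exact conjugate of the length map used for the muscles.

`L0` of each virtual muscle is not tabulated anywhere; the package defines
it as the muscle-tendon length at `theta = 0`, which puts the operating
point on the force-length plateau during quiet stance. Both choices
(`gamma0 = 90°`, `L0` at neutral) are configuration values, not hard-coded.

Activation is a square wave over the five gait stages (2 = early swing,
3 = late swing, 4 = early stance, 5 = late stance, 6 = powered
plantarflexion): the anterior muscle is active through swing and early
stance (0.93/0.28/0.31 in profile 1; 0.63/0.48/0.51 in profile 2), the
posterior muscle only during powered plantarflexion (0.44 and 0.69), and
late stance is a passive gap. At most one muscle is active at any instant.
An optional trailing-mean ramp (`smoothing_window`) can soften the square
wave; it is off by default, matching the stepped activation of the original
controller (whose abrupt transitions are a documented source of damping
fluctuations).

The net ankle moment is `(Fss_P*r_P - Fss_A*r_A)/100` N·m, plantarflexion
positive — so the reported push-off moments are positive peaks while
plantarflexion angles are negative, matching the sign conventions of the
gait literature. An additive viscous compensation term
(`resistance_gain * dtheta/dt`, default gain 0) stands in for
hardware-resistance compensation, which is device-specific and out of scope.

Ankle power is the product of the mass-normalised moment and the angular
velocity taken in the plantarflexion-positive sense (`-dtheta/dt`, central
differences): with both factors in the same rotational convention, power is
positive (generation) during push-off. The raw product of the
plantarflexion-positive moment and the dorsiflexion-positive angle rate
would be negative there, which is why the sign convention is stated
explicitly.

## The synthetic gait generator

No subject recordings are published, so the generator emulates the
qualitative ankle-angle waveforms of the study's figures rather than any
individual's data. Each cycle is a monotone cubic Hermite spline
(Fritsch-Carlson, zero slope at extremum knots) through named control
points, so the configured extremes are the exact waveform extremes; the
boundary points of every cycle are pinned at 0°, so concatenated cycles
join continuously. Stride-to-stride variability is seeded Gaussian noise
(SD 0.25° by default) on the interior control points only.

* **Level walking** (heel-strike at 0%): a -4° controlled-plantarflexion
  dip at 7%, mid-stance dorsiflexion of +8/+10/+12° peaking at 47%, a
  plantarflexion peak of -8/-13/-19° at 60% (toe-off), and a +3° swing
  return. The three speed classes use stride durations of 1.40/1.15/0.95 s.
  The plantarflexion peaks span the -8° to -19° range reported for level
  walking at 0.75-1.65 m/s.
* **Stair ascent**: two controlled-dorsiflexion/plantarflexion excursions
  per step cycle — a +12° pull-up excursion at 15%, a +3° relief dip, a
  +17° second dorsiflexion at 48% — then a plantarflexion peak of -17° at
  68%, deeper and later than level walking, within the reported -15° to
  -19° stairs range. Step-cycle duration is `120/cadence` s (step-over-step
  gait) and the stance fraction 0.65.
* **Transition bout**: two level strides, four stair steps, two level
  strides (eight cycles), joined continuously; the downstream controller
  sees only the angle stream.

Stage labels are assigned by cycle fraction, not by torque thresholds:
early stance covers the first fifth of stance (controlled plantarflexion),
late stance runs to 75% of stance (controlled dorsiflexion), and powered
plantarflexion covers the rest of stance, beginning near peak dorsiflexion
— the phase structure used by powered-prosthesis state machines. The exact
boundary fractions of the original device are not published; these defaults
are configuration, not a claim about the device.

What the generator does **not** emulate: ground contact and loading (stage
labels are ideal, not sensor-derived), double-support timing asymmetries,
kinematic noise correlated within a stride, subject-specific waveforms, and
any kinetic quantity — moments come only from the model. Tests that pass on
synthetic gait therefore validate the controller's response to realistic
angle inputs, not its behaviour on a physical prosthesis.

## Stride analytics

Heel strike is defined as the stage 3 to 4 label transition (the package
does not model ground contact); strides are segmented there, partial
leading/trailing cycles dropped, and each stride is linearly interpolated
onto 100 equally spaced cycle points. Per-stride metrics are the peak
mass-normalised moment, the peak plantarflexion angle during stance, the
peak (signed maximum, switchable to maximum-magnitude) ankle power, and the
stride duration, aggregated as mean ± SEM; the SEM of a single stride is
reported as 0 with a flag. The first stride of a simulated bout starts from
fully relaxed muscles — a state no walking human is in — and is treated as
a warm-up transient in the terrain comparisons, as in treadmill protocols.
Net-moment peaks per cycle are counted as local maxima of the 100-point
profile with prominence of at least 10% of the cycle's moment range,
restricted to stance: one dominant push-off peak per level-walking stride,
and a pull-up plus a push-off peak per stair cycle.

## Tuning and sensitivity

`fit_parameters()` reproduces the fitting procedure: a bounded local
quasi-Newton search (`stats::optim`, L-BFGS-B) maximising the R² of the
controller's moment output against a reference trace, over a free list
restricted to `P0`, spring and damping constants — activation levels were
user-tuned on the device, not optimised, and are excluded by default.
Because the experimental torque recordings are not published, reference
traces for testing are self-generated from known parameters, making the
generating values an exact oracle: from ±25% starting offsets the free
parameters are recovered to well under 5% with R² ≥ 0.99. The optimizer's
stopping tolerance is deliberately tight (`factr = 1e4`): the objective has
a shallow ridge along which `P0` and `Cce_s` partially compensate, and a
loose tolerance stops on the ridge.

`sensitivity_scan()` perturbs every tabulated parameter one at a time —
muscle constants, attachment geometry, and the activation levels — over
fractions 0.5% to 250% of nominal and reports the R² of the perturbed
controller against the nominal output. The row at fraction 1.0 is the
self-comparison (R² = 1 exactly); perturbations that violate a model
invariant, such as an activation scaled above 1, are recorded as missing
values rather than aborting the scan.

## Problem sizes and tolerances

The test suite exercises bouts of 4-8 cycles at 500 Hz (about 2,300-5,300
samples, two muscles each), 5-15 s single-muscle protocols, a 1,000-point
geometry grid, 10^5 random states for the velocity identity, and the full
18-parameter x 10-fraction sensitivity grid; the whole suite runs in well
under a minute. Key tolerances: the superposition identity holds to 1e-12
relative to the operand scale; isometric convergence is asserted at 0.1%
with the rotational residual below 1e-6 * P0; moment arms match numerical
derivatives to 1e-6 relative; oracle deviation stays under 1% of P0 with a
dt-halving ratio in [1.5, 2.5].

## Known limitations

* The closure of the pulley kinematics is one consistent choice among
  several the published equations admit; the original real-time code is not
  available for comparison. All history-dependence claims are made for this
  closure.
* Residual force enhancement decays exponentially here, whereas in muscle
  experiments it persists for many seconds; the model captures the
  direction and amplitude-ordering of the effect, not its persistence.
* The linear damper makes the force-velocity relation symmetric within each
  direction; there is no activation dynamics (calcium kinetics), so
  square-wave activation produces instantaneous `Fce` steps.
* The biarticular function of the gastrocnemius (knee coupling) is ignored,
  as in the original controller.
* Simulated moment magnitudes depend on the stage-boundary defaults of the
  synthetic generator and should not be read as predictions of device
  torque; only the shape properties (peak structure, reciprocity, terrain
  adaptation) are asserted by the tests.
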