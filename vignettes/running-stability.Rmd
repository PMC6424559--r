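---
title: "How the runner keeps from falling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the runner keeps from falling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Human running is mechanically unstable: a point-mass biped on massless legs
that replays a fixed force pattern diverges from its periodic motion after
an arbitrarily small perturbation. Yet people run for thousands of
consecutive steps. This package implements both halves of a program for
explaining that robustness from data:

1. **Inference**: mine the step-to-step variability in ordinary treadmill
   recordings (per-foot ground reaction forces plus marker kinematics) for
   the linear feedback rules that map center-of-mass (COM) state deviations
   at one flight apex onto corrective actions in the next stance.
2. **Synthesis**: install those rules on a minimal 3D point-mass biped —
   one variant commanding leg force directly, one producing force through a
   Hill-type muscle — and verify that the closed loop is stable, survives
   motor noise, and regenerates variability with the same structure, so
   that the pipeline recovers the controller it was given.

All internal computation is nondimensional: mass, gravity and maximum leg
length are 1, so forces are in body weights, lengths in leg lengths and
time in units of `sqrt(leg length / g)` (about 0.33 s for a 1.05 m leg).
`run_scales()` converts at the boundary.

# The biped and its hybrid dynamics

The body is a point mass; the stance leg is massless and telescoping, so
the ground reaction force (GRF) has magnitude `F_leg` and is directed from
the foot to the body:

    x'' = F_leg (x - x_foot) / l
    y'' = F_leg (y - y_foot) / l
    z'' = -1 + F_leg (z - z_foot) / l

Flight is parabolic free flight, handled in closed form (momentum and
energy are conserved exactly there). Each step has three phases: flight
from apex to touchdown, stance, and flight from takeoff to the next apex.
Touchdown occurs when the body-to-target-foot distance equals the
commanded landing leg length (nominally 95% of maximum); takeoff when the
leg reaches maximum length. If the foot is already within reach at apex
the runner goes directly into stance; if takeoff happens with downward
velocity, there is no apex and the end-of-stance state substitutes as the
controller's input.

Numerical choices: stance integration uses `deSolve`'s `lsodar` at
relative/absolute tolerance 1e-10 with root-based event localization
(event timing feeds the stability estimates, so it is the precision-
critical part); flight events are closed-form roots polished to 1e-13.
"Falling" is not defined by the mechanics alone, so the package uses: body
height below 0.2 leg lengths, leg shorter than 0.1, no touchdown solution
before reaching the ground, or a stance exceeding three nominal durations.
These are configurable in `biped_model()`.

# The control waveform and the nominal gait

Within a stance, the commanded leg force (direct variant) or muscle
activation (muscle variant) is a two-term sine series

    A1 sin(pi t / T_stance) + A2 sin(2 pi t / T_stance),

rectified at zero. The second harmonic skews the profile so the force peak
need not sit at mid-stance — exactly the freedom needed for within-step
vertical control (below). During perturbed stances the waveform keeps the
nominal stance duration as its time base; the actual stance still ends at
the takeoff event.

`solve_nominal_gait()` finds a periodic, left-right mirror-symmetric gait:
10 unknowns (stance initial state, A1, A2, stance and flight durations)
against 10 conditions (landing length, takeoff length, periodicity of the
velocity and touchdown height, and four targets: forward speed, step
period, step width, peak leg force), solved by Levenberg-Marquardt
(`minpack.lm`) to residual < 1e-6. Default targets describe treadmill
running at 2.9 m/s on a 1.05 m leg: nondimensional speed 0.90, step period
1.07 (0.35 s), step width 0.095 (0.10 m), peak force 2.5 body weights.
These are package configuration in `gait_targets()`, chosen as typical
values for that speed, not fitted quantities.

# Vertical control in closed form

Net vertical impulse between two apexes must equal the gravity impulse
(vertical velocity is zero at both ends), so vertical position cannot be
controlled by the net impulse. An idealized step — stance of duration
`T_step`, triangular vertical force — makes the alternative transparent:
impulse balance forces the peak to 2 body weights for any duration
(`triangular_peak_force()`), and double integration gives the apex-height
change

    dz = ((T_step - t_peak)^2 - t_peak^2) / 6,

zero for a mid-stance peak, negative when the peak is delayed
(`apex_height_change()`, `tpeak_for_height_change()`,
`half_impulse_split()`). Moving impulse from the first to the second half
of stance lowers the next apex without changing the total. This module is
also the sign oracle for the vertical feedback in the full model.

# The human-derived controller

The packaged gain set (`human_gain_set()`, also shipped as
`inst/extdata/gains_human.yaml`) carries the feedback laws estimated from
pooled human treadmill data, per stance side:

- sideways foot placement: `d(xf - xs) = 0.95 dvx` (left stance; 1.00
  right) — step in the direction of the sideways velocity error;
- fore-aft foot placement: `d(yf - ys) = 0.42 dvy - 0.76 dza` (left; 0.39
  and -0.83 right) — step further forward when moving faster, land with a
  steeper leg from a higher apex;
- landing leg length: `dl = 0.3 dza` — land shorter when the apex is low
  (a step-up analog);
- the apex-to-apex return map over a right stance (its left counterpart is
  the sagittal mirror `diag(-1,1,1) K diag(-1,1,1)`), including entries
  not significantly different from zero, preserved with their flags.

The waveform feedback `(dA1, dA2) = G (dvx, dvy, dza)` is not given by the
data directly; `fit_force_gains()` chooses G so the model's one-step
apex-to-apex map — probed by central finite differences (default step
1e-4, chosen against the 1e-10 integrator floor) — best matches the target
return map in the Frobenius norm, followed by Gauss-Newton refinement on
the actual finite-difference map. Two structural facts emerged and are
worth recording:

- The sideways row of the target map cannot be matched by waveform changes
  at all (a symmetric force-magnitude change barely moves sideways
  velocity); its residual (~0.1) is carried entirely by the foot-placement
  law. Both variants share this limit.
- The muscle variant's compliant plant makes the unconstrained fit choose
  very large activation gains, which leave the linear regime under
  ordinary noise amplitudes and destabilize the loop. The muscle fit
  therefore uses a ridge penalty (`lambda = 0.5` relative to the
  sensitivity scale in `fit_model_controller()`), trading fidelity in the
  strongly coupled fore-aft/vertical entries for a loop that remains
  linear at operating amplitude. The direct-force variant uses the
  unconstrained fit. We read this as a statement about control authority:
  a muscle-tendon actuator cannot impose arbitrary return maps through its
  activation without leaving its linear range.

With the fitted gains the stride (two-step) spectral radius is well below
one for both variants; open loop it exceeds one. Sideways deviations decay
faster than fore-aft ones, and energy-adding perturbations are repaid with
net negative leg work on the first recovery step (`work_loop()`).

# The Hill-type muscle and why it tolerates noise

The muscle variant produces leg force through a muscle-tendon unit (MTU):
active contractile element (CE) with Gaussian force-length (width `w`) and
linear force-velocity (max shortening rate `vmax`, eccentric cap 1.5)
factors, a linear series tendon and a linear parallel element. The CE
length is a dynamic state during stance; its rate comes from inverting the
linear force-velocity relation against the tendon-minus-parallel force.

The mounting matters: MTU length *decreases* with leg length
(`l_mtu = 1.6 - l_leg`), the abstraction of a knee extensor whose MTU is
stretched when the knee flexes. Leg compression then stretches the tendon
(spring-like stiffness) and lengthens the CE (eccentric force rise —
damping), and extra activation shortens the CE, extends the leg and
thereby releases tendon stretch — negative feedback on the activation
command itself. With the opposite mounting the same components *amplify*
noise. Package defaults (`muscle_params()`: Fiso 10 BW, vmax 1, tendon
stiffness 12 BW per leg length, chosen so the nominal gait peaks near half
activation, leaving feedback headroom) give roughly a three-fold
attenuation of activation noise relative to the direct-force variant, and
within-stance rejection of touchdown-height errors. All muscle parameters
are package defaults — the underlying experiments constrain none of them.

This intrinsic (preflex) stabilization is what separates the variants
under motor noise: at the calibrated noise level the muscle-driven runner
completes thousands of steps while the direct-force runner falls within a
few hundred.

# Motor noise and its calibration

Noise enters as in the motor-control literature: one Gaussian
multiplicative factor `(1 + eps)` per stance scaling the whole commanded
force/activation profile, plus additive Gaussian offsets on each commanded
foot placement (`noise_spec()`, applied by `apply_noise()`). Defaults
(eps s.d. 0.025; placement s.d. 0.01 sideways, 0.008 fore-aft leg lengths)
were calibrated once so that the muscle-variant closed loop reproduces the
experimental scale of apex-height variability — a standard deviation near
0.005 leg lengths (~5 mm) — and then frozen. The generator's defaults *are*
the study conditions; they are not adjusted per experiment.

# The synthetic experiment and the inference pipeline

`generate_gait_data()` re-samples the noisy closed-loop simulation onto
the dual-rate clocks of a split-belt treadmill lab: per-foot 3D GRFs at
1000 Hz equivalent and marker-like kinematics (COM proxy, one marker per
foot) at 100 Hz, in SI units, with optional measurement noise (defaults:
force 0.002 BW, positions 1e-4 leg lengths — lab-grade) and optional slow
sinusoidal force drift. Swing-foot markers follow a quintic path toward a
*predictable* landing spot (previous anchor plus mean stride), with the
realized target — which carries the feedback and the noise — blended in
only during the final flight phase, after the controller's decision at
apex. On-disk format: `forces.tsv`, `kin.tsv`, `meta.json`
(`write_gait_data()` / `read_gait_data()`); external recordings can be
mapped into this schema by any loader producing those three files. What
the generator does *not* emulate: soft-tissue artifact, force-plate
crosstalk, marker occlusion, trunk and limb inertia, air drag — so passing
recovery tests here demonstrates the pipeline's correctness on data whose
generating process matches its assumptions, not robustness to every
real-world artifact.

`fit_gait_controller()` runs the pipeline: COM velocities by integrating
the mass-normalized net force (integration constants from zero trial
means), drift removal, stance segmentation at a 0.05 body-weight vertical
force threshold (~30 N), apex location at the downward zero crossing of
vertical velocity (end-of-stance substitution flagged when absent), apex
height from the kinematic channel, per-step features (impulses,
half-stance vertical impulses split at the stance midpoint, foot placement
relative to the COM at touchdown, landing leg length, 20 phase-binned GRF
values per component), per-side OLS regression families, apex-to-apex
return maps with stride eigenvalues, and phase-dependent GRF
sensitivities. Deviations are taken about per-side (and per-subject, when
pooling with `pool_features()`) means. Raw p-values are reported without
multiple-testing correction.

**Drift removal.** The classical treatment high-passes the integrated
velocities near an eighth of the step frequency. On this generator's data
that filter is not innocuous: the closed loop's fore-aft deviations decay
slowly (a per-step persistence near 0.7 under the ridge-fitted muscle
controller), so much of their power lies below such a cutoff, and removing
it inflates every velocity-referenced gain estimate — by tens of percent —
through regression dilution in reverse. Smoothing the integrated velocity
itself (a stiff-spline drift estimate) softens but does not remove the
problem: any smoother flexible enough to track drift absorbs some of the
slow genuine deviations. The default estimator therefore anchors the
integration to the kinematic channel: the drift is estimated as a stiff
smoothing spline (about one degree of freedom per 40 steps) of the
*difference* between the force-integrated velocity and the marker-derived
velocity. The true gait motion is present in both and cancels in the
difference, so the spline sees only drift plus white differentiation
noise, and the corrected velocity is unbiased — against ground truth the
apex-velocity deviations come back with correlation 1.00 and regression
slope 1.00 on both horizontal channels. The velocity-only spline, the
Butterworth filter (any cutoff) and plain mean removal remain available
via the `drift` argument of `com_kinematics_from_grf()` for sensitivity
analyses and for force-only datasets.

**A threshold pathology worth knowing about.** The muscle variant's leg
force does not snap to zero at takeoff: the tendon releases through the
slow contractile element, and the force tail dwells within a few
thousandths of a body weight of the 0.05 BW detection threshold for tens
of milliseconds. Any threshold detector is ill-posed in that regime, and
the half-stance impulse split — which hinges on the detected stance
midpoint — inherits the sensitivity: its regression slope against apex
height cannot be pinned against an independent oracle, only against the
same detector run on noiseless data. The shipped tests treat it exactly
that way; all other per-step statistics are well-posed and are checked
against independent oracles.

Companion analyses: `predictor_power_vs_phase()` (how well COM state vs
swing-foot state predict the upcoming placement across the previous step),
`bootstrap_gain_vs_n()` (gain spread vs sample size; the s.d. follows the
inverse square-root law, so tenfold precision costs a hundredfold sample),
`symmetry_check()` (mirror consistency of left/right gains), and the
station-keeping comparison (`predictors = "apex+position"`), which on
position-blind synthetic data raises impulse R-squared by well under 1.5
percentage points.

# Problem sizes and reproducibility

The shipped tests run the full chain at sizes chosen so a
3-standard-error recovery criterion is meaningful: 2000-step recordings
for parameter recovery, 1000-step endurance runs, and the same scales in
`scripts/acceptance.R` (which regenerates everything from an installed
package and a single `--seed`). Every stochastic element — motor noise,
measurement noise, bootstrap — flows from explicit seeds; same-seed runs
are bit-identical.

A note on what "recovery" compares. Gains the controller holds explicitly
(foot placement, landing length) are recovered against their programmed
values. Emergent regression families (impulse slopes, half-stance
impulse slopes, the return maps) are compared against the same regression
run on the simulator's exact per-step quantities (`truth_gains()`):
under closed-loop motor noise a simple-regression slope reflects the
joint step-to-step process — deviations and corrective outputs share
noise pathways — so a one-perturbation derivative is not the quantity the
estimator targets. The half-stance impulse slopes make the point vividly:
the deterministic sensitivity to apex height is about -1, while the
closed-loop regression slope is near -3.5, because the same profile-noise
draw that perturbs the apex also perturbs the half impulses. Human data
analyzed this way have exactly the same property, which is worth keeping
in mind when reading such coefficients as controller gains.

# Known limitations

- The sideways row of the return map is foot-placement-only; the model
  under-corrects sideways velocity (one-step slope about -0.9) relative to
  the human estimate (about -1.0), a plant-geometry effect that the
  waveform feedback cannot close.
- The muscle fit's ridge leaves the fore-aft/vertical block of the return
  map farther from its target than the direct-force variant; fore-aft
  deviations consequently decay over several strides rather than within
  one, and the model's phase-dependent fore-aft modulation concentrates
  in the propulsion half of stance where the human curves concentrate in
  braking.
- The anchored velocity estimator requires the kinematic COM channel; on
  force-only recordings the fallback drift removers re-introduce a
  fore-aft attenuation bias of order the drift-window flexibility.
- The half-stance impulse split rides on a takeoff detection that is
  ill-posed when the leg force dwells at the detection threshold (this
  plant's muscle variant does exactly that), so its regression slopes are
  reproducible but not oracle-checkable (above).
- One muscle per leg, no activation dynamics, no trunk or limb inertia,
  flat rigid ground only (terrain enters as apex-height offsets).
- Absolute-position (station-keeping) control is deliberately absent from
  the controller, and the pipeline's position predictors exist only to
  verify its absence.
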