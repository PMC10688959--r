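---
title: "biomechfit: models, priors and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{biomechfit: models, priors and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Optical motion capture gives labeled 3D marker trajectories
$\bar{x}_{1:T}$ and, when force plates are present, ground reaction
forces (GRF). Turning these into subject-specific biomechanics requires
solving several coupled estimation problems: *scaling* a generic
skeleton to the subject, *registering* the markers (estimating each
marker's true fixed offset $p^{(i)}$ in its segment frame), *inverse
kinematics* (joint coordinates $q_t$ per frame), and — given GRF —
segment masses and *inverse dynamics* with residual root loads driven
toward zero. biomechfit automates the whole chain as a sequence of
linear initializations feeding non-convex maximum-a-posteriori (MAP)
refinements, so that no hand-tuned starting point is needed.

# Skeleton model

The skeleton is a tree of rigid segments connected by free (6-DOF
root), ball (3-DOF, intrinsic XYZ Euler) and revolute (1-DOF) joints;
the world is Y-up with gravity $(0, -9.80665, 0)\,\mathrm{m/s^2}$ and
all internal units are SI with radians (degrees only in MOT files).
Per-segment scale vectors $s$ act elementwise on joint offsets, marker
offsets and COM offsets; inertia follows a box or cylinder model whose
tensor scales as mass times squared scaled dimensions. Euler ball
joints have the usual gimbal caveat; the synthetic motions keep the
middle angle well below 80 degrees. The mass matrix comes from the
composite-rigid-body algorithm over the elementary 1-DOF chain;
inverse dynamics from Newton–Euler segment balances with recursive
velocity/acceleration propagation. Both are cross-checked in the test
suite against independently assembled $\sum_b J_b^\top \mathcal{I}_b
J_b$ oracles and a forward-dynamics round trip.

# Marker fitting

The kinematic stage maximizes
$P(\bar{x}\,|\,q_t,s,p)\,P_s(s)\,P_p(p\,|\,\bar p)$ with Gaussian
terms: observation noise $\sigma_{\bar x}$ (1 cm), a scale prior
(mean 1, SD 0.1 per axis, optionally conditioned on stated height or
mass by a linear-Gaussian rule), and a marker-placement prior that is
tight for anatomical-landmark markers (1 cm) and loose for tracking
markers (5 cm). The inner problem over $q_t$ makes this bilevel; the
package exploits the first-order-stationarity reformulation in two
ways:

1. **Exact alternation**: per-frame damped Gauss–Newton inverse
   kinematics (which enforces the stationarity condition to machine
   accuracy) alternating with bounded quasi-Newton steps on $(s, p)$.
   The first rounds keep $p$ pinned at $\bar p$: releasing the marker
   offsets too early lets them absorb a tilted root orientation (the
   pelvis-tilt ambiguity), stranding the refinement in a poor basin.
2. **Joint Levenberg–Marquardt**: the full problem over
   $(s, p, q_{1:F})$ on a uniform frame subsample (default 80 frames,
   capped at 200) is a separable nonlinear least squares, so the
   damped normal equations are solved with per-frame Schur elimination
   of the $q_t$ blocks — the bundle-adjustment structure. This follows
   the shallow, coupled valleys (root tilt traded against hip/lumbar
   angles and marker offsets) that first-order methods crawl along.

A final full-rate IK pass with the optimized $(s, p)$ restores
stationarity at every frame and produces the reported marker RMSE
(over visible marker–frame pairs only; missing markers are masked,
never imputed).

## Initialization

Functional joints are estimated directly from marker clusters: child
markers are expressed in a parent-anchored frame (per-frame orthogonal
Procrustes), a deterministic linear least-squares center-of-rotation
estimate starts a moving-sphere refinement
$\sum_{t,i}(\lVert \bar x_t^{(i)}-c_t\rVert - r_i)^2$, and an axis fit
additionally estimates per-frame unit axes with constant signed
parallel and perpendicular marker distances. For noise-free hinge
motion the center-of-rotation system is rank 2 — the center is only
determined up to sliding along the axis — so it is solved by
pseudo-inverse about the cluster centroid rather than rejected. The
axis fit *succeeds* when its RMS residual is within 1.5x the sphere
residual and the per-frame axes agree to 10 degrees on average;
success passes an axis (line) constraint downstream, failure means
out-of-plane motion, in which case the unambiguous sphere center is
passed instead. Scale initialization then fits uniform per-segment
scales to the markers plus the joint constraints (point distance, or
perpendicular distance to the axis line) on up to 50 frames, clipped
to $[0.5, 2]$, alternating twice with IK. Per-axis scales are untied
only in the bilevel stage.

# Dynamics fitting

Given GRF (resampled to marker timestamps by linear interpolation;
plate-to-foot assignment by plate rectangle, a 5 cm foot-height
threshold and a 10 N force threshold), the smoothed kinematic solution
is made dynamically consistent in three linear-algebraic steps plus a
final mass optimization.

**Jerk smoothing.** Each coordinate minimizes
$\lVert q - q_{in}\rVert^2 + w\lVert D_3 q\rVert^2$ with $D_3$ the raw
third difference (null space: quadratics, which pass through
unchanged). The default weight places the half-power cutoff at 6 Hz
independent of frame rate — chosen for gait bandwidth; acceleration
noise grows as the 2.5 power of this cutoff while gait torque content
lives below ~6 Hz.

**Linear COM/mass fit.** Under semi-explicit Euler, the COM trajectory
is affine in $\zeta = (z_1, \dot z_1, \mu)$ with $\mu$ the inverse
mass, because $\ddot z = \mu f + g$. The minimum-norm least-squares
fit of the stacked system to the kinematic COM trajectory recovers the
total mass and an exactly force-consistent COM path; the pelvis is
then translated so the model COM tracks it (an exact update: the COM
moves one-for-one with root translation). A flight-only trial makes
$\mu$ structurally unidentifiable (its column vanishes); the fit
falls back to the prior mass with a warning.

**Angular fit.** The same scheme extends to the root rotations
$\theta_t$: with centers of pressure fixed, a COM displacement
$\Delta z$ changes the GRF moment by $\Delta z \times f_t$, giving the
linear response $\Delta\ddot\theta_t = M_{rr}^{-1}E^\top(f_t\times
\Delta z_t)$ with $M_{rr}$ the root-rotation block of the mass matrix
and $E$ the Euler-rate map. The nominal $\ddot\theta_t$ comes from the
root rows of the equations of motion with the non-root accelerations
held at the current trajectory; mass matrix, Coriolis and gravity
terms are frozen per linearization. The stacked affine system in
$\xi = (z_1,\dot z_1,\theta_1,\dot\theta_1)$ is solved by
pseudo-inverse against the observed COM/rotation trajectories and
re-linearized until the reconstructed trajectory changes by less than
$10^{-6}$ (max norm), at most 50 iterations; on the synthetic trials
convergence takes 15–30 iterations. The offset vector is built by
rolling the recursion out with zero initial conditions, which the test
suite checks against the closed-form block assembly to $10^{-10}$.

**Final mass optimization.** The root residual wrench is *exactly
linear* in the segment masses (inertia is mass-proportional under the
box/cylinder models), so the mass update is a ridge least-squares
problem: residual rows weighted by $1/\sigma_f$ (5 N) and
$1/\sigma_\tau$ (2 N·m), Gaussian priors pulling mass fractions toward
the segment nominals (SD 3% of total mass) and the total toward the
linear-fit mass (SD 1 kg), masses clamped at 0.5 kg. The root
trajectory is then re-fit under the new mass distribution. Scales and
marker offsets are deliberately held at their marker-fit values in
this stage: the residual loads are governed by the masses and the root
trajectory, and on synthetic trials further $(s,p)$ movement buys no
residual reduction while risking the marker fit (the marker-RMSE
degradation budget is 2 mm). Each sub-step is accepted only if the
joint objective (marker + priors + residual penalty) does not
increase.

Residual metrics use central-difference accelerations (one-sided at
the two endpoint frames, which are excluded from the RMS), report the
RMS root force and world-frame root moment, and normalize by peak GRF
magnitude (force) and peak GRF times mean COM height (torque) — the
conventional percentages.

# The synthetic world

The generator emulates a simulated walking evaluation in which the
answer is known and residual loads are zero by construction. A subject
is drawn with per-axis scales uniform in $\pm 10\%$, total mass
uniform in $\pm 10\%$ of 72.5 kg distributed by nominal fractions, and
true marker positions displaced up to 5 mm (anatomical) / 20 mm
(tracking). Joint trajectories are smooth periodic patterns (walking
in place at a given cadence) with realistic ranges — hip flexion
±17°, knee flexion 3–55°, arm swing with 9–37° elbow flexion so that
upper-arm axial rotation is observable from the wrist markers. The
pelvis height keeps the lower foot at ~1–2 cm via a smooth
soft-minimum, and the stance weight transfers smoothly to whichever
foot is lower, so a loaded foot is always near the ground. The GRF is
*derived*: the root wrench required by inverse dynamics with no
external load is converted to per-foot plate wrenches (force at the
foot's ground projection, remainder in the plate free moment), which
makes the trial dynamically consistent to machine precision under the
same finite-difference convention the metrics use. Marker noise is
i.i.d. Gaussian (default 1.5 mm per axis) plus Bernoulli occlusion
(default 2%) and an optional sinusoidal soft-tissue artifact on
thigh/shank tracking markers (off by default).

What a green test does **not** establish: the surrogate gait has no
ground-contact mechanics, no soft-tissue artifact by default, no force
plate calibration errors, and stationary (in-place) walking; real
marker sets have labeling errors and longer gaps. Accuracy numbers on
this world are therefore upper bounds on what the same pipeline
achieves on laboratory data.

# Known limitations and open choices

* **Identifiability of scales and offsets.** Roughly half of the
  per-axis scales of the default 13-segment model carry no marker
  information (foot height, pelvis thickness, ...). They sit at the
  prior mean while the synthetic truth is drawn ±10%, so median
  noise-free recovery plateaus near 2% (scales) / 2 mm (offsets)
  regardless of optimization effort — we verified that running the
  refinement 4x longer lowers the objective below its value at the
  ground truth without moving these medians. Joint angles and torques
  are insensitive to these flat directions.
* **Prior defaults** ($\sigma_s = 0.1$, anatomical 1 cm, tracking
  5 cm, observation 1 cm) are configurable; an anthropometric fit to a
  population dataset is out of scope, but `condition_priors()` shifts
  the scale prior for stated height/mass.
* **Final-stage decision variables** are masses + root trajectory (see
  above); full $(s, p, q)$ re-optimization under the residual penalty
  is a straightforward extension point.
* The angular-fit offset vector re-derives the Coriolis/gravity/GRF
  integration from the stated recursion; force-plate pose-error and
  drift terms are not modeled.
* C3D input, muscle models, contact simulation and closed kinematic
  loops are out of scope; markers with missing frames are masked, not
  gap-filled.
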