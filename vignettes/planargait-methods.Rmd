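---
title: "Muscle-driven planar gait simulation: models, rewards and stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-driven planar gait simulation: models, rewards and stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planargait)
```

# Scope and model

`planargait` implements a sagittal-plane musculoskeletal walker and the
analysis chain that studies how agonist–antagonist coactivation and the
joint stiffness it produces relate to walking stability on slippery and
uneven ground. The full-body problem (31 degrees of freedom, 92 muscles,
motion-capture reference data, multi-day reinforcement-learning runs) is
reduced to a desk-scale planar instance: seven rigid segments (a
head–arms–trunk lump, two thighs, shanks and feet), a planar free base plus
six revolute joints, eighteen Hill-type muscle–tendon units (nine per leg,
tagged to the agonist/antagonist groups used by the coactivation analysis),
and three contact spheres per foot (one calcaneus, two toe). Segment masses
and lengths follow standard anthropometric fractions scaled to a 65.4 kg,
1.712 m body. A synthetic periodic reference gait at 1.34 m/s replaces the
(unavailable) motion-capture input.

Conventions: x forward, y up, rotations about +z, radians internally
(file readers convert a declared-degrees `.mot` at the boundary); joint
angles are anatomical (hip flexion, knee flexion, ankle dorsiflexion
positive) and mapped to rotations through per-joint axis signs.

# Muscle–tendon model

Each actuator is a Hill-type muscle fiber in series with an elastic tendon.
The dimensionless curves are Thelen-style closed forms: a Gaussian active
force–length curve `exp(-(l/l_opt - 1)^2 / 0.45)`; an exponential passive
curve reaching the maximum isometric force at 60 % fiber strain; a Hill
hyperbola on the concentric side joined C¹ to an eccentric branch that
plateaus at 1.4; and a tendon curve with a quadratic toe blending into a
linear region, normalised to carry exactly F0 at 4.9 % strain. All
constants are exposed through `hill_curve_constants()`.

Activation follows the first-order dynamics
`da/dt = (u - a) / tau(u, a)` with `tau_act * (0.5 + 1.5 a)` on the rise
and `tau_deact / (0.5 + 1.5 a)` on decay (defaults 10 ms / 40 ms). Note
one consequence used by the tests: because the time "constant" scales with
activation, a single 40 ms decay step from `a = 1` falls *below*
`exp(-1)`, and a 50 ms rise reaches ~0.96 rather than 0.99 — the classical
single-exponential intuition only bounds these trajectories.

During dynamic simulation the fiber state is integrated with a damped
equilibrium rule: the normalized fiber velocity solves
`a f_L(l) f_V(x) + beta x + f_P(l) = f_T / cos(alpha)` with damping
`beta = 0.1`, which removes the bang-bang fiber collapse a pure
force–velocity inversion produces around slack and keeps passive walkers
force-free at rest. The quasi-static analysis path
(`solve_mtu_equilibrium()`) instead finds the fiber length that balances
tendon and fiber force exactly (damped Newton with a bisection fallback on
`[0.2, 1.8] l_opt`; residual below `1e-6 F0`); a rigid-tendon mode is
provided for closed-form checks. Pennation uses the constant-thickness
model but is zero for every bundled muscle: with nonzero pennation the
series-stiffness identity below is only approximate, and the stiffness
oracle requires it exactly.

## Fiber operating point

MTU parameter calibration is anchored to the standing pose: the tendon is
exactly slack there and the fiber sits at 0.85 of its optimal length. This
puts the working range of every muscle on the ascending limb of the active
force–length curve, where fibers have positive length feedback — the
regime in which coactivation stiffens a joint. Knee-crossing muscle paths
carry a via point just distal to the joint (a polyline stand-in for
patellar/retinacular routing, since true wrapping surfaces are out of
scope), which keeps moment arms near-constant over the motion range.

# Joint stiffness

With the moment arm defined as `r = dL/dtheta` (L the MTU path length,
computed as the summed Euclidean distance over path points, and `r`
obtained analytically from the path-point Jacobians), a muscle of tension
F contributes

```
K = dr/dtheta * F + K_MTU * r^2,      K_MTU = (1/K_M + 1/K_T)^-1
```

to the joint stiffness, where `K_M` is the slope of the fiber force along
the length axis at fixed activation (the force–velocity multiplier is
evaluated at the state's velocity but not differentiated) and `K_T` the
tendon curve slope over the slack length. The total joint stiffness is the
sum over muscles; it equals the derivative of the net muscle moment
`sum r F` with all fibers re-equilibrated, which is exactly how the test
suite checks it (central finite differences, relative error below 1e-3
over hundreds of randomized planar configurations). Fiber stiffness may
legitimately be negative on the descending limb; the per-muscle breakdown
flags this rather than clipping it.

Two practical observations, both visible in the reported numbers. First,
at low activation the geometric term `dr/dtheta * F` can dominate and make
the instantaneous stiffness of a joint slightly negative — straight-line
muscle routing has destabilising curvature that real joints counter with
wrapping geometry; this is an acknowledged planar-model limitation, and the
coactivation-stiffens-the-joint property is therefore demonstrated at the
ankle, whose short-fibered, long-tendoned muscles with near-constant moment
arms are the clean spring-like regime. Second, both unit views are always
carried (`Nm/rad` and `Nm/deg`, related by `pi/180`): the source material
is internally inconsistent about the unit of the stiffness targets (the
running text says Nm/rad where the objective table and reported knee values
say Nm/deg), so the package defaults to Nm/deg for targets and reports,
with the unit always explicit.

Trial-level reporting averages the instantaneous stiffness over the whole
gait cycle (stance plus swing); a stance-only view can be had by
subsetting the per-frame table.

# Coactivation index

For two activation traces on a shared uniform grid,

```
CI (%) = 100 * 2 * int min(a_ag, a_ant) / (int a_ag + int a_ant)
```

with trapezoidal integrals. Group-level indices average the CI over all
agonist-by-antagonist muscle combinations; the thigh index is the mean of
the vastus–biceps femoris and vastus–semitendinosus pair indices, the
shank index the mean of tibialis anterior–soleus and tibialis
anterior–gastrocnemius. Two all-zero traces define CI = 0 with a warning.
Trial-level indices are computed over whole episodes and averaged across
trials; a phase-resolved variant bins the traces by gait phase (default
100 bins). Whether the original analysis aggregated per cycle or per trial
is not documented; trial-level is the default here.

# Rewards

The imitation objective is
`r_track = 0.65 r_pos + 0.1 r_vel + 0.15 r_end + 0.1 r_com` with
exponential kernels `exp(-c * SSE)` and coefficients 0.4 (joint angles,
rad), 0.000625 (joint velocities, rad/s), 1.25 (end-effector positions, m)
and 0.5 (whole-body COM position, m). Angle errors enter in radians — with
degree errors the 0.4 coefficient would annihilate the kernel. Shaping
adds `r_A = exp(-sum a_i^2)` and
`r_S = exp(-sum_j (S_target_j - S_j)^2)` over hip, knee and ankle, with
variant weights (w_track, w_A, w_S): STANDARD (1, 0, 0), ACT (0.9, 0.1, 0),
STIF0–STIF3 (0.9, 0.05, 0.05) with targets 0, 5.0, 7.5, 10.0 per joint,
and ACT_RANDOM sharing ACT's weights but drawing the training-ground
friction uniformly from [0.2, 0.8] per episode. `r_A` sums over however
many muscles the model has; an opt-in rescaling by `92 / n_muscles` keeps
its magnitude comparable to the full-body muscle set. The stiffness `S`
inside `r_S` is the instantaneous analytic joint stiffness at every
control step, averaged over the left and right limb of each joint
(bilateral averaging chosen; per-leg values are available from the
breakdown API).

# Simulator

Physics runs at 1 kHz (semi-implicit Euler on the rigid-body tree, mass
matrix assembled from point Jacobians) under 100 Hz control. Ground
contact is penalty-based: normal force `k delta (1 + c * penetration
rate)` (k = 1.5e5 N/m, c = 1 s/m, a Hunt–Crossley-style damped spring)
with regularised Coulomb friction `-mu N tanh(v/0.005)`, whose magnitude
can never exceed `mu N` — the friction-cone property the tests check on
every logged frame. Joint limits are soft (300 Nm/rad beyond the range).
Contact constants were calibrated only against the static-support and
sliding oracles. A fall is a pelvis below 60 % of standing height or a
trunk pitch beyond 60°, evaluated per control step; heel strikes are
rising edges of the calcaneus-sphere vertical force through 5 % body
weight with a 100 ms refractory period. Terrain is flat at friction 0.8
for a 5 m run-in, then either drops to a slippery friction or becomes a
seeded two-octave gradient-noise heightfield, amplitude-normalised so the
maximum height equals the height scale and blended in over 0.3 m so the
run-in stays exactly flat.

# Synthetic reference gait

Joint trajectories are normative sagittal curves (hip ~30° flexion to
-10° extension, double-bump knee flexion peaking near 60° in swing, ankle
-15°/+10°) band-limited to at most four Fourier harmonics, so the
reference velocities are exact spectral derivatives; the left leg is the
right delayed by half a cycle. Pelvis height is solved per frame so the
lower foot sphere grazes the ground, then softened to a physiologic
~2–3 cm vertical excursion (the compliant contact absorbs the residual
mismatch); COM and end-effector trajectories follow by forward kinematics,
making every tracking-error symbol mutually consistent. The cycle duration
(1.1 s) is an assumption — the source never states one — and the EMG-like
activation fixture places raised-cosine bursts with typical on/off timing
per muscle group, plus optional truncated Gaussian noise.

What the generator does *not* emulate: subject-specific kinematics,
frontal/transverse-plane motion, soft-tissue artefact, or EMG
electromechanical delay. Tests passing against this reference show the
pipeline is internally correct, not that it reproduces any particular
participant.

# Training at desk scale

The PPO learner (clipped surrogate, GAE(0.95), advantage normalisation,
Adam, entropy bonus 1e-3) is written in plain R against the C++ simulator.
Hyperparameters are community defaults (clip 0.2, gamma 0.99); none are
reported in the source material. Episodes start at a random reference
frame with the frame's joint angles and velocities, the policy's own
output as initial excitations and activations, and fibers initialised at
equilibrium (an "optimal fiber length" mode is available; in the standing
pose the two coincide by construction). Full-scale settings (200
environments, 40 000 samples per update, 65 000 updates, 512/256 networks)
remain selectable but are days of compute; the desk defaults are 8
environments, 1–2 s horizons, 64/32 networks, and tens of updates.

Two desk-scale effects deserve honesty. First, the per-step tracking
score barely moves over short runs while the *episode-cumulative*
tracking return clearly improves: the learner's fastest progress channel
is surviving longer (stiffening the legs), which raises the cumulative
objective even while the per-step mean dips. Learning progress is
therefore monitored on the episode return, which is the quantity PPO
optimises; for a controller that does not fall the two coincide. Second,
the stiffness-target kernel `exp(-(S_target - S)^2)` is numerically zero
when the measured stiffness is far from target (targets of 5–10 against
measured values near zero give exponents of hundreds), so at desk scale
only STIF0 — whose target is at the operating point — receives a usable
gradient; STIF1–STIF3 differ from each other only below double precision.
The ordinal stiffness ordering across fine-tuned variants at desk scale is
driven by STIF0's downward pressure and is asserted as a 3-seed majority.

# Known limitations

* No controller at desk scale survives a full 20 s trial: the scripted
  reference-tracking muscle PD falls within about a second, and the
  balanced-tonus standing controller (static-optimization tonus, knees
  against their extension stops, low-pass COM ankle feedback) stands for
  a bit over two seconds, which is the packaged regression fixture. The
  40 ms deactivation lag and the foot's small backward COP margin defeat
  the simple feedback schemes tried. Survival experiments therefore
  produce small or zero counts, and the ordinal survival assertions hold
  as (meaningful) ties.
* Straight-line muscle routing gives slightly negative low-activation
  stiffness at the knee (see above).
* The contact model is compliant, not hard-contact; penetration of a few
  millimetres under body weight is by design.
* Statistics helpers (Pearson chi-squared without continuity correction,
  Bonferroni as `min(1, p * n_pairs)`, one-way ANOVA) are thin wrappers
  over base R with the degenerate cases pinned down (zero-variance groups
  give p = 1 with a flag; empty margins route to Fisher's exact test).

# Problem sizes used by the tests

The default test suite runs the stiffness oracle on 125 random
configurations, the equilibrium residual oracle on ~80 random states,
3–5 s episodes for the contact and determinism checks, and the scaled-down
replication with 8 environments, 80 standard + 3 x 40 fine-tuning updates
per seed over three seeds; the acceptance script trains 60 + 2 x 30
updates and runs 10 s survival trials. These sizes are the package's
defaults for interactive use; every one of them scales up by configuration.
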