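---
title: "Motor control of mastication with Soft Actor-Critic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor control of mastication with Soft Actor-Critic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`posselt` couples three components:

1. a **muscle-driven surrogate of the human jaw** — a 3-DOF point mass at
   the lower mid-incisal point actuated by 24 Hill-type point-to-point
   muscles in 12 bilateral pairs, restrained by passive temporomandibular
   (TMJ) ligament springs, gravity and viscous damping;
2. a **Soft Actor-Critic (SAC) agent** trained to drive the mid-incisal
   point to arbitrary targets inside a Posselt-style 3D envelope of motion,
   using a three-term reward (log-distance reaching, muscle-force
   regularization, bilateral-symmetry penalty);
3. a **performance-analysis platform** quantifying a trained policy by
   range of motion (ROM), metabolic efficiency (ME), agility (Ag), accuracy
   (Ac) and symmetry (Sym), with reward-coefficient sweeps and excitation
   trace recording.

This vignette documents the model equations, the tunable parameters and
their defaults, the numerical choices, and what the synthetic surrogate
does and does not capture.

# The jaw surrogate

## State and actuation

The jaw's configuration is abstracted to the 3D position $P$ of the lower
mid-incisal point (mm; $x$ lateral-right, $y$ anterior, $z$ superior,
origin at the closed maximum-intercuspation pose, ICP). Rotational degrees
of freedom, tooth contact and condylar guidance are not modeled; their
kinematic consequences are emulated by the force landscape of the anchored
muscles and ligaments. Each muscle is a point-to-point Hill-type spring
from a fixed skull-frame anchor to the mid-incisal point, with tension

$$T = f_{\max}\left(a\, f_l(\tilde l)\, f_v(\tilde v) + k_p
\max(0, \tilde l - 1)^2\right), \qquad
\tilde l = l / l_{\mathrm{opt}}, \quad \tilde v = v / v_{\max},$$

where $a \in [0,1]$ is the activation (identical to the neural excitation
— no activation dynamics, no neural delay), $f_l$ is a quadratic active
force-length curve of width $w = 0.56$ peaking at the optimal length, and
$f_v$ is a Hill hyperbola with curvature $a_h = 0.25$ for shortening,
continued by a linear lengthening branch capped at 1.5 (matched slopes at
zero velocity). Muscles only pull; tension is clamped at zero.

Each TMJ ligament is a point-to-point spring with slack: zero tension up
to `rest_length + slack_offset` (slack 7.5 mm beyond the closed pose) and
linear-elastic beyond, with stiffness $EA/L_0$ (Young's modulus 2.45 MPa).
The ligaments bound wide opening and pull the jaw back toward closure —
with zero excitation, passive recoil closes the jaw.

## Forward dynamics

Newton's equations for the 200 g point mass are integrated with a
semi-implicit (symplectic) Euler scheme at $\Delta t = 1$ ms: the velocity
update treats viscous damping and the force-velocity dependence of the
muscle tensions implicitly (a 3×3 Newton solve with the analytic velocity
Jacobian of the Hill terms), then the position advances with the new
velocity. When muscle forces are velocity-independent this reduces to the
familiar
$v' = (v + \Delta t\, F/m)/(1 + \Delta t\, c/m)$, $P' = P + \Delta t\, v'$.
The implicit treatment is required for stability: a fully activated muscle
contributes velocity damping through $f_v$ that is far stiffer than the
explicit stability limit at $\Delta t = 1$ ms.

## The generated model and its calibration

`generate_jaw_model(seed, asymmetry_scale)` lays out the left side by
functional role (six elevators with long, nearly vertical lines of action;
four depressors anchored infero-posteriorly; one protruder and one
"lateral" compartment per side emulating the inferior and superior lateral
pterygoid), mirrors it across the sagittal plane and perturbs the right
side's anchors and maximum tensions by a uniform relative factor within
`asymmetry_scale` (default 2%), emulating the left-right asymmetry of real
masticatory systems. The lateral compartments anchor *contralaterally*, so
exciting a left-side channel produces right laterotrusion, as in
physiological function.

Two design constraints shaped the default parameters:

* **Rest equilibrium.** With the spec'd ligament slack, the ligaments are
  force-free at ICP, so gravity must be balanced by the passive Hill
  terms. A calibration step solves a 3×3 linear system for multiplicative
  scales on the passive stiffness of (left elevators, right elevators,
  depressors + protruders) such that the net passive + gravity force at
  the origin is exactly zero. The rest pose is therefore an exact, stable
  passive equilibrium even for asymmetric models.
* **Force economy and controllability.** The reward's force term operates
  on tensions in newtons with weights of order one, so the tension needed
  to *hold* any pose inside the envelope must remain a few newtons — it
  equals the passive resistance at that pose, which the long elevator
  lines of action (small relative stretch at full opening) and the soft
  ligament cross-section keep low (≈ 7 N at maximum opening, < 1 N at
  rest). Independently, the *sensitivity* of position to excitation
  (mm per unit excitation) sets the positional noise floor under a
  stochastic policy; it scales with $f_{\max}$ over passive stiffness.
  The elevator and depressor strengths follow physiological magnitudes
  (100–200 N and 20–60 N); the pterygoid compartments, whose strength the
  generator does not tie to literature values, default to a few newtons so
  that the envelope extremes are reached near full excitation and the
  map from excitation to position stays well-conditioned for learning.

Damping defaults to near-critical for the stiffest eigendirection of the
passive stiffness at rest ($c = 2\sqrt{k_{\max} m}$), computed by finite
differences at generation time.

## Envelope of motion

Eight canonical constant excitation patterns (configuration data defined
on roles and muscle names, not learned) drive the jaw to equilibrium at
the labeled extremes ICP, E, PR, LL, RL, RCP, R and MO. The default
patterns produce a tear-drop-like envelope with ≈ 48 mm opening, ≈ 15 mm
laterotrusion per side and ≈ 11 mm protrusion; its convex hull (volume
≈ 5 cm³) defines the feasible target region. Only the eight end-points
bound the hull; intermediate border trajectories are not used. Because the
surrogate has no tooth-contact constraints, positions slightly outside the
declared envelope are physically reachable; training targets are always
drawn inside the hull.

# The reinforcement-learning problem

## Episodes, observations, actions

Each episode starts at rest (ICP, zero excitations) with a target $\hat P$
sampled inside the envelope: with probability 1/2 a renormalized-uniform
convex combination of all eight end-points, otherwise a uniform convex
combination of two end-points drawn with replacement (so 6.25% of episodes
target an exact end-point). The observation is the 33-vector
(excitations, position, velocity, target), positions normalized by the
envelope half-extents and velocities by 100 mm/s. An action is a per-muscle
excitation increment capped at ±10% of the excitation range; excitations
are clipped to $[0,1]$. Each action is followed by $K = 20$ physics
substeps (50 Hz control). An episode ends when the mid-incisal point comes
within 100 µm of the target or after $T = 100$ actions.

## Reward

$$r_{t+1} = -w_u \log(\lVert \hat P - P_{t+1} \rVert_2 + \epsilon)
            - w_r \lVert f_{t+1} \rVert_2
            - w_s \lVert e^l_{t+1} - e^r_{t+1} \rVert_1$$

with distances in mm, tensions in N and $\epsilon = 10^{-3}$ mm (unstated
in the source formulation; chosen to cap the reward at the scale of the
100 µm success radius). $w_u = 1$ fixes the reward scale; $w_r$ and
$w_s$ are the experimental knobs. Because tensions enter in newtons, the
meaning of $w_r$ is coupled to the surrogate's force scale (see the
calibration discussion above).

## Soft Actor-Critic

The agent is a canonical SAC learner, written from scratch (no deep
learning framework in the stack): a Gaussian policy with two 256-wide
rectified hidden layers and parallel mean / log-standard-deviation heads
(log σ clamped to $[-20, 2]$), twin critics (3-layer, 256-wide MLPs) with
EMA target copies (τ = 0.005), a 10⁶-capacity uniform replay ring, Adam,
Xavier initialization, discount γ = 0.99, fixed temperature α = 0.3, and
a learning rate decaying from 10⁻³ by 0.999995 per update with floor
4 × 10⁻⁴. Actions are squashed with tanh; the log-density includes the
change-of-variables correction and is computed over the squashed variable
in $[-1,1]$, with the ±0.1 excitation-delta bound applied at the
environment boundary — the convention of reference SAC implementations,
which keeps critic inputs and entropy magnitudes well-scaled. Bootstrap is
masked only on success termination; timeouts bootstrap, since running out
of steps is not an environment-terminal event. Updates begin once the
buffer holds one batch, optionally preceded by a uniform random-action
warm-up phase (default 2000 steps) that seeds the buffer with diverse
excitation states; all randomness (initialization, exploration noise,
target sampling, replay draws) flows from R's RNG, so a seed fully
reproduces a run.

Gradients are hand-derived and verified against central finite differences
in the test suite (both critic and actor paths, including the tanh and
clamp corrections).

# Performance metrics

* **ROM**: 100 × (convex-hull volume of every mid-incisal position visited
  during the evaluation episodes) / (reference envelope hull volume). The
  hull code is an incremental 3D convex hull written for this package
  (no installed dependency provides one); it is cross-checked against a
  rejection-sampling volume oracle.
* **ME**: inverse of the mean over all pooled evaluation steps of the mean
  24-muscle tension (1/N).
* **Ag**: inverse of the total simulated time to visit the waypoint cycle
  ICP → MO → E → RL → E → LL → E → PR → ICP, each within 1 mm; unreached
  waypoints contribute the full episode timeout and set a failure flag.
* **Ac**: inverse of the mean final distance over the 21-target protocol
  (distances averaged first, then inverted — robust to one near-zero
  distance dominating).
* **Sym**: inverse of the pooled mean L1 gap between left and right
  excitation sub-vectors, with a 10⁻⁶ floor so perfectly symmetric traces
  report a capped maximum.

ME and Sym pool steps across episodes (concatenation-invariant); this
convention is asserted by tests. The 21-target protocol uses the eight
end-points, the centroid, and six face + six interior points seeded from
the hull.

# Problem sizes and desk-scale training

Training runs in compiled code at roughly 4–15 k environment steps per
minute on one CPU core, depending on network width, batch size and the
update-to-data ratio. The desk-scale configurations used by the package's
own tests and the acceptance script are: hidden width 48–64 (the 256-wide
architecture remains the configured default of `sac_config()`), batches of
128, three gradient updates per environment step
(`updates_per_env_step`, exposed precisely because the single-update
baseline is known to be sample-inefficient), a 5000-step random warm-up,
and budgets of 3–5 × 10⁴ environment steps for accuracy-oriented runs and
3 × 10⁴ steps per model for coefficient sweeps. Sweeps assert only the
directions of the metric-versus-coefficient correlations, not their
magnitudes: correlation magnitudes depend on subject-specific anatomy and
multi-day training budgets that a desk-scale surrogate cannot and should
not reproduce. Reaching accuracy at these budgets plateaus at the
millimeter scale (the reference study's sub-millimeter accuracies were
obtained after millions of environment interactions); the learning curves
recorded in the fitted object make the remaining gap explicit.

What passing desk-scale tests show: that the implementation of the
mechanics, the reward, the learner and the metrics is correct and that the
closed training loop improves reaching on the surrogate. What they do not
show: physiological fidelity of learned excitation patterns, transfer to
subject-specific anatomy, or the asymptotic accuracies attainable with
multi-million-step budgets.

# Numerical choices and degenerate inputs

* Muscle force contributions drop out (with a warning at the R level) if
  the mid-incisal point coincides with an anchor (degenerate direction).
* `equilibrium_position()` requires the speed to stay below tolerance for
  a 50-step dwell, so transient zero-crossings do not count as
  convergence; hitting `max_time` raises an explicit non-convergence
  error.
* Degenerate (coplanar) hulls report volume 0 with a warning; an envelope
  with non-positive hull volume is an error (the model is unusable for
  training).
* Infinite-metric sentinels (zero tension, zero distance) are serialized
  as a capped value (10⁶) plus an explicit flag, never as raw infinity.
* The log-σ head is clamped to $[-20, 2]$; clamped entries receive zero
  gradient.

# Known limitations

* The jaw is a translational point mass: no rotation, no occlusal
  contact, no condylar kinematics; RCP/R/E are emulated positions, not
  contact-defined poses.
* The excitation-to-activation map is the identity; no activation
  dynamics or neural delay.
* The ligament is a single straight spring per side (no wrapping).
* Asymmetry is a scalar relative perturbation, not anatomical shape
  difference.
* Desk-scale budgets plateau above the accuracies that large-budget
  training attains; the accuracy-oriented tests use the surrogate's
  default conditions and small networks.
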