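---
title: "A hierarchical neuromechanical model of planned walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical neuromechanical model of planned walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitplanr)
```

## The model

`gaitplanr` simulates human walking as the interplay of three layers.

**Biomechanics.** A 3-D skeleton with 14 degrees of freedom: six free-body
coordinates of the trunk (the head-arms-trunk segment, 54.2 kg of the
80 kg body) and, per leg, hip abduction/adduction, hip flexion/extension,
knee flexion and ankle plantar/dorsiflexion. Segment masses, lengths and
inertias follow standard anthropometric proportions for a 1.80 m adult and
live in `inst/extdata/default_model.yaml`. Ground contact acts through
four spheres per foot (two heel, two ball) with a nonlinear spring-damper
normal force and regularized Coulomb friction. Each leg carries ten
Hill-type muscle-tendon units (soleus, tibialis anterior, gastrocnemius,
vastus, hamstrings, rectus femoris, gluteus, hip flexor, hip ab- and
adductor) with Gaussian-like force-length, hyperbolic force-velocity, a
quadratic-toe series elastic tendon and first-order activation dynamics.

**Spinal control.** Every muscle is innervated by a generic stretch
reflex, `S = [K_l(l + u) + K_v(v + u') - h]+`, operating on delayed
spindle estimates of normalized fiber length and velocity; the threshold
shift `u` is the descending command. During stance three functional
modules are added: positive force feedback on the antigravity muscles
(compliant leg), a force-modulated compliant-hip reflex in which the
biarticular hamstrings and rectus femoris act as a trunk-balancing spring
whose stiffness scales with the sensed leg force, and a velocity-gated
guard against knee overextension. The components sum, rectify, and clamp
to `[floor, 1]`. Proprioceptive delays are distance-based: 20 ms for
ankle-level signals, 10 ms for knee, 5 ms for hip and trunk.

**Supraspinal planning.** A finite state machine organizes stance, early
swing and late swing per leg. A gait is specified by eight high-level
control parameters: swing hip-flexion and knee targets at the end of early
and late swing, a single swing ankle target, the swing duration, the
stance hip-flexion reference (trunk lean), and a constant desired forward
trunk acceleration (propulsion). Swing joints follow minimal-jerk
(quintic) trajectories toward their targets; the hip targets are modulated
by balance feedback on the trunk-to-center-of-pressure offset, its
velocity and the trunk orientation, independently in the sagittal and
frontal planes. For the stance leg, the propulsion target is converted to
desired accelerations of the five-joint stance chain (including the
kinematic ball-of-foot hinge) by a constrained pseudoinverse that enforces
zero sagittal trunk angular acceleration and zero torque at the ball hinge
and the hip-abduction joint.

**Internal models** turn plans into descending commands: chain
inverse dynamics (mass-matrix map for stance, full gravity-and-interaction
inverse dynamics for swing), a muscle-force distribution that minimizes
the summed squared muscle forces subject to the moment-arm equality and
nonnegativity, inversion of the Hill characteristics, inversion of the
first-order activation dynamics, and inversion of the stretch reflex to
obtain the threshold shifts.

## Parameters that matter

* `control` (8 + `v_init`): the gait definition; `v_init` only sets the
  onset speed.
* `spinal` (27 values): stretch-reflex gains and resting level, the two
  compliant-hip gains, three compliant-leg force-feedback gains, three
  knee-guard constants, ten tonic baseline drives, three pathway delays,
  the stimulation floor and the two activation time constants.
* `balance` (8 gains): position/velocity foot-placement feedback, early
  and late swing, sagittal and frontal.
* Two fixed reflex constants are not part of the optimized vector: the
  frontal-plane analog of the compliant-hip reflex on the stance hip
  ab/adductors (`c_lat`), and a pre-swing gastrocnemius drive
  (`s_preswing`) that flexes the knee and plantarflexes during double
  support so the trailing foot unloads before swing initiation.

## Numerical choices

Fixed-step semi-implicit Euler integration at `dt = 1e-4 s` (muscle and
contact dynamics are stiff; fixed stepping makes runs bit-reproducible);
control ticks at 1 kHz. The minimal-jerk plans are integrated as an
internal plan state pulled toward the sensed state with a small per-tick
gain (`plan_feedback`) and evaluated with a short lookahead
(`plan_lookahead`) — replanning directly from delayed sensed states forms
an unstable high-gain loop through the sensorimotor delays and actuation
lag. Planned accelerations and commanded torques are clamped to
physiological magnitudes (`qdd_cap`, `tau_cap`). The force distribution is
solved with per-muscle upper bounds at the sensed force capacity
`F_max f_l f_v`, which keeps the Hill inversion consistent (`S <= 1`); the
exported `distribute_forces()` also offers the plain nonnegativity-only
problem. The skeleton carries anatomical soft stops and a small passive
joint damping. Degenerate stance postures where the propulsion system
loses rank fall back to a damped pseudoinverse with a warning.

## Optimization, generalization, transitions

`optimize_gait()` runs a covariance-matrix-adaptation evolution strategy
(written in R, verified on standard test functions) over either all 43
parameters + `v_init` (unconstrained cost: distance before falling, then
steadiness) or the 8 control parameters + `v_init` against a staged cost
for a target step length and cadence (tolerances 0.02 m/s and
2 steps/min). Gait metrics are measured over the last 10 s of a 20 s walk:
cadence from the mean inter-strike interval, step length from consecutive
contralateral heel-strike positions, speed from the forward center-of-mass
displacement, and steadiness (`d_steady`) as the mean RMS difference of
the kinematic state at consecutive same-side heel strikes (forward
position excluded, so a perfectly periodic gait scores zero).

A basis-point library collects learned gaits indexed by their achieved
cadence and step length. `interpolate_gait()` generalizes to unlearned
gaits by a convex, inverse-distance-weighted combination of the five
nearest library rows, with each axis standardized by the library's
standard deviation so the mixed units (steps/min versus meters) do not
bias the neighborhood. `run_transition_walk()` switches the eight control
parameters at fixed times irrespective of the gait-cycle state — spinal
and balance parameters are never touched — and `library_pca()` examines
the dimensionality of the learned control-parameter sets (z-scored 8-D
rows).

## The synthetic library fixture

`generate_fixture_library()` builds a deterministic stand-in library whose
control parameters are an affine function (plus optional small noise) of
gait targets spread over cadence 85–140 steps/min and step length
0.53–0.97 m — the achieved ranges of walking models of this class. It
emulates a perfectly converged library: achieved gaits equal the targets
and parameters vary smoothly. Real libraries are scattered, multimodal
(two gaits close in cadence-step-length space can use distant control
strategies) and carry optimization noise, so tests passing on the fixture
validate the interpolation, transition and PCA logic — not the
generalization power of a learned library.

## Problem sizes used by the tests and the acceptance script

The packaged analyses are deliberately small: 20 s evaluation walks with a
10 s metric window, a 30-point synthetic library, transition experiments
with a handful of draws, and tiny CMA-ES budgets in the test-suite
self-checks. Full optimizations (tens of thousands of evaluations) run
through `scripts/optimize_gait.R` and regenerate the shipped
`optimized_gait.yaml`.

## Known limitations

* The closed loop is sensitive to the reflex and balance parameterization;
  from generic starting points the model typically falls within a second
  or two, and reaching steady gaits requires long evolutionary
  optimization (hours of CPU per run). The shipped parameter set reflects
  the best optimization result produced with the package so far and is the
  honest current state of the closed-loop experiments.
* No arms or head segments, a single ankle degree of freedom (no ankle
  roll, which limits lateral balance at slow gaits), flat rigid ground
  only, and no metabolic-cost considerations.
* The steadiness measure and the fall criterion are package definitions
  (each isolated in one function), chosen conservative and configurable.
* Whether the early-to-late swing split is time-based (as implemented,
  50% of the swing time by default) or target-reach-based is an open
  modeling choice; time-based was selected for determinism.

```{r example, eval = FALSE}
model <- load_model()
params <- optimized_params()
sim <- run_simulation(params, model, duration = 20)
gait_metrics(sim)
plot_simulation(sim)

lib <- generate_fixture_library(30, seed = 1)
ctl <- interpolate_gait(110, 0.70, lib)
tidy(library_pca(lib))
```
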