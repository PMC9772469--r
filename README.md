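# gaitplanr

`gaitplanr` is a 3-D neuromechanical model of human walking in which a
small set of high-level, voluntary motor-plan parameters — not a re-tuning
of low-level reflexes — selects the gait. A supraspinal layer plans
minimal-jerk swing-leg trajectories toward target joint angles, a constant
forward propulsion for the stance leg and a trunk reference lean; internal
inverse models (chain inverse dynamics, least-squared-force muscle
distribution, Hill-model and stretch-reflex inversion) transform those
plans into descending commands; the spinal layer integrates the commands
with a generic stretch reflex per muscle plus stance-specific modules
(compliant-leg positive force feedback, force-modulated compliant-hip
trunk balancing, knee-overextension guard) that drive 20 Hill-type muscles
on a 14 degree-of-freedom skeleton with sphere-based ground contact.

A gait is defined by 8 control parameters

| parameter | meaning |
|---|---|
| `theta_hipfl_early`, `theta_knee_early` | swing hip/knee targets, end of early swing (rad) |
| `theta_hipfl_late`, `theta_knee_late` | swing hip/knee targets, end of late swing (rad) |
| `theta_ankle` | swing ankle target (rad) |
| `t_swing` | swing duration (s) |
| `theta_ref_hipfl` | stance hip-flexion reference = trunk lean (rad) |
| `a_x` | constant forward propulsion (m/s²) |

plus an initial speed `v_init` used only at onset. The swing hip target is
modulated online by balance feedback,
`theta = theta_tar + c_d d + c_v v − phi_trunk`, on the delayed
trunk-to-center-of-pressure offset. Gait-specific parameters are learned
with a covariance-matrix-adaptation evolution strategy against staged
costs (fall distance → speed error → cadence error → steadiness); learned
gaits form a basis-point library that generalizes to unlearned gaits by
inverse-distance-weighted interpolation of the five nearest neighbors in
cadence–step-length space, and real-time transitions switch the 8 control
parameters mid-walk without touching the spinal side.

## A worked example

```r
library(gaitplanr)

model <- load_model()        # 1.80 m / 80 kg, 10 muscles per leg
model
#> <walker_model>
#>   DoF: 14  total mass: 80.0 kg  standing trunk CoM: 1.289 m
#>   muscles: 20 (10 per leg)  contact spheres: 8

sim <- run_simulation(optimized_params(), model, duration = 20)
sim
#> <walker_sim>
#>   simulated 3.55 s of 20.00 s requested; walked 3.12 m
#>   fell at t = 3.55 s (x = 3.12 m, cause: height)
#>   heel strikes: 19
```

The record reports how long and how far the model walked, every heel
strike with its position, the gait-phase transitions, ground reaction
forces and per-muscle stimulations. `gait_metrics(sim)` summarizes step
length (m), cadence (steps/min), speed (m/s) and the stride-to-stride
steadiness measure `d_steady` over the last 10 s. (The printed run shows
the current shipped parameter set covering about three metres before
losing balance — finding parameter sets that walk steadily and
indefinitely is exactly the optimization problem the package poses, and
it takes long evolutionary runs; see `scripts/optimize_gait.R`.)

Library logic works independently of long optimizations:

```r
lib <- generate_fixture_library(30, seed = 1)   # synthetic basis points
ctl <- interpolate_gait(110, 0.70, lib)          # 5-NN convex interpolation
round(ctl[c("t_swing", "a_x", "v_init")], 3)
#> t_swing     a_x  v_init
#>   0.594   0.702   1.351
glance(library_pca(lib))
#> # A tibble: 1 × 4
#>   n_components first_two first_four n_gaits
#>          <int>     <dbl>      <dbl>   <int>
#> 1            8     0.993      0.998      30
```

Plotting: `plot_simulation()`, `plot_grf()`, `plot_gait_library()`,
`plot_transition_walk()`, `plot_library_pca()` (also via `autoplot()`).
A command-line interface with `simulate`, `optimize`, `generalize`,
`transition`, `pca` and `fixtures` subcommands ships in
`inst/cli/gaitplan.R`.

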