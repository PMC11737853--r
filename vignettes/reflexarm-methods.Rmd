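---
title: "Spinal reflex control of a planar arm: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spinal reflex control of a planar arm: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexarm)
```

## Overview

`reflexarm` simulates goal-directed upper-limb movement as the closed-loop
interaction of three components:

1. **Supraspinal commands** — one cycle of a sinusoid per elbow muscle
   group, `c(t) = a sin(2πf t + φ) + d` for `t < 1/f`, holding the offset
   `d` afterwards. The flexor group (long and short biceps, brachialis)
   shares one command, the extensor group (the three triceps heads) the
   other; the anterior deltoid receives none.
2. **A modular spinal network** — one motoneuron (MN) per muscle plus
   interneurons and Renshaw cells, wired by six pathway templates:
   monosynaptic Ia stretch reflex (Ia-MN), disynaptic reciprocal Ia
   inhibition of antagonists (Ia-INa), heteronymous Ia excitation of
   synergists (Ia-MNs), disynaptic II static stretch reflex, disynaptic Ib
   autogenic inhibition and Renshaw recurrent inhibition (RN). Every
   neuron is a leaky rate unit, `τ ṙ = −r + σ(Σ w_i r_i(t − δ_i))`, with
   τ = 1 ms and a steep logistic σ (slope 8, offset 0.5). Only the final
   connection onto the MN carries a tunable weight; upstream synapses are
   fixed at 1. Heteronymous weights are divided by the number of such
   connections the MN receives.
3. **A planar two-joint arm** — shoulder and elbow, actuated by seven
   Hill-type muscles with constant moment arms and rigid tendons, under
   configurable gravity (magnitude scale and in-plane direction rotation)
   and optional hand-force perturbations.

Muscle spindles and Golgi tendon organs close the loop through
Prochazka-style rate models,
`r_Ia = sgn(v)·4.3·max(|v|,0.01)^0.6 + 2(l − l₀) + 10` Hz,
`r_II = 13.5(l − l₀) + 10` Hz and `r_Ib = F/F_max`, normalised to [0, 1]
and delayed by 30 ms (an exact ring buffer on the 1 ms integration grid).

## Parameters that matter

| Parameter | Default | Units | Note |
|---|---|---|---|
| neuron time constant τ | 1 | ms | fast-response large neurons |
| sigmoid slope D / offset x₀ | 8 / 0.5 | — | near on-off behaviour |
| sensory delay δ | 30 | ms | upper-limb afferent latency |
| spindle baseline | 10 | Hz | tonic rate at l = l₀, v = 0 |
| activation τ_act / τ_deact | 10 / 40 | ms | asymmetric calcium dynamics |
| integration step dt | 1 | ms | matches τ |
| command amplitude a | [0.05, 0.7] | — | optimiser bound |
| command frequency f | [0.1, 0.8] | Hz | one cycle spans the movement |
| pathway weights (sweeps) | [0, 1] | — | final MN connection only |
| pathway weights (optimised) | [0, 2] | — | group-level in scenario S4 |
| loss penalty w_pen | 5 | — | end-window activation penalty |
| perturbation | 30 N, 30 ms | — | world-frame force at the hand |

The plant is a deliberate stand-in (the reference experiments used a
scaled OpenSim model that is not available): upper arm 0.30 m / 2.0 kg,
forearm-plus-hand 0.35 m / 1.7 kg, centres of mass at 45 % of segment
length, uniform-rod inertias, 0.15 N·m·s/rad viscous damping per joint,
soft joint limits, and constant moment arms of ±25 mm (shoulder) and
±20 mm (elbow). Hill curve shapes are standard Thelen-style forms, pinned
exactly in the `hill_force()` documentation for testability. None of the
published headline tables can be reproduced numerically with this plant;
the package therefore checks *orderings and trends*, not values.

## Design choices made where the model was open

**Sigmoid sign.** The source prints a decreasing logistic, which would
invert every excitatory pathway; the conventional increasing form is used.

**Fiber reference posture.** Fiber lengths follow the linear map
`l = l_ref − Σ ma_j (θ_j − θ_ref,j)`. We anchor `l_ref = l₀` at the *rest
posture* of the baseline movement (shoulder 0°, elbow 20°) rather than at
elbow mid-range. With a mid-range anchor the one-sided passive force
curves drag the passive arm to ≈ 87° elbow flexion — contradicting the
modelling premise that passive structures and reflexes return the arm
toward its resting position. With the rest-posture anchor the passive arm
sags only a few degrees against passive tension, spindles sit at their
10 Hz baseline at rest, and stretch reflexes pull back toward rest.

**Afferent normalisation.** "Scaled by their maximum" is implemented with
*fixed* maxima computed from a physiological envelope (|v| ≤ 300 mm/s,
|l − l₀| ≤ 50 mm), giving Ia ≈ 242 Hz and II = 685 Hz. A running maximum
would make the controller gain time-dependent and irreproducible. A
consequence: the 10 Hz baseline survives normalisation as a small tonic
drive (≈ 0.04) to the cord at rest.

**Delay placement.** The 30 ms delay is applied once, to afferent signals
entering the cord; interneuron-to-MN transmission costs one integration
step. Renshaw cells are modelled as interposed leaky neurons with only
the RN→MN weight exposed.

**Deviation metric.** Implemented as printed: the maximal post-onset
excursion of the (perturbed) elbow angle from its value one step before
onset, with an absolute value so upward and downward forces register
alike. Note that this includes the movement's natural post-onset
excursion; it is a comparative, not absolute, robustness measure.

**Speed arc length (SAL).** Implemented literally as printed,
`−Σ √(1/N² + v̂²)` with the elbow speed peak-normalised for amplitude
invariance. Zero motion gives exactly −1; magnitudes grow with the number
of samples, so SAL values are only comparable at a fixed time base.

**S4 weight grouping.** The synaptic optimisation searches four weights —
Ia-MN and Ia-INa, each shared across the flexor group (including the
anterior deltoid, a flexor) and across the extensor group — matching the
group-level reporting of the reference experiments.

**CMA-ES.** Implemented natively (population 4 + ⌊3 ln n⌋, log-rank
weights, initial step 25 % of each range in normalised coordinates, box
constraints via clip-plus-quadratic-penalty). Deterministic per seed.

**Sensitivity analysis.** Saltelli cross-sampling over a Sobol'
quasi-random sequence (Joe-Kuo direction numbers, seeded digital shift)
with Saltelli-2010/Jansen estimators; N(2D+2) rows with second order
(7168 at N = 512, D = 6). The desk-scale default is N = 64.

**EMG processing.** 5th-order Butterworth low-pass at 5 Hz designed via
the bilinear transform (verified against reference coefficients), applied
forward-backward (zero phase) so activation-window timing is undistorted;
envelopes are normalised by the identically processed MVC maximum.
Activation windows threshold each group-mean envelope at 85 % (flexors)
or 65 % (extensors) of its own RMS.

## What the synthetic data emulates — and what it does not

The recorded trajectories and EMG behind the reference experiments are
not deposited. `make_target()` generates their stated envelope: a
minimum-jerk reach-and-return (2.8 s, 78° elbow ROM) and a closed-loop
circular movement (1.3 s, 40° ROM) with a small (10°) shoulder excursion,
at 100 Hz. `make_synthetic_emg()` adds per-muscle burst envelopes
phase-locked to the sign of the elbow acceleration, Gaussian noise and a
synthetic MVC trace; the medial triceps is excluded (deep muscle).
The generators do not mimic subject-specific kinematic noise, pose
estimation artefacts, real EMG spectra or crosstalk. A green test on
synthetic data therefore establishes internal consistency of the
pipeline, not agreement with human recordings.

## Numerical behaviour and known limitations

- **Integration.** Semi-implicit Euler at 1 ms for the arm; exact
  exponential updates for neurons and activations. Passive mechanical
  energy drifts < 0.5 % over 1 s; the passive plant matches an
  independent absolute-angle Lagrangian RK4 oracle.
- **Reflex tremor.** The spindle velocity law `4.3 |v|^0.6` has unbounded
  local gain at v = 0. Combined with the 30 ms delay and the steep
  sigmoid this produces a small sustained oscillation (physiologically: a
  tremor/clonus-like limit cycle) around rest when stretch reflexes are
  at full strength. A displaced arm returns *toward* rest, but its
  residual speed stays of order 0.1–1 rad/s, and trajectories with
  the full reflex loop engaged are sensitive to the integration step.
  Trend tests (smoothness, perturbation deviation) are robust to this;
  step-refinement convergence is asserted for the command-driven plant.
- **Ranking reproduction.** With this self-contained plant the dominant
  pathway orderings of the reference sensitivity tables do not all
  reproduce: in particular, perturbation deviation here responds most
  strongly to the homonymous Ia-MN weight rather than the heteronymous
  Ia-MNs weight (all elbow muscles share identical moment arms, which
  makes the homonymous reflex geometrically as effective as the
  heteronymous sum). The corresponding acceptance check is left failing
  rather than tuned.
- The minimal-SC tremor also slightly penalises the optimised tracking
  loss, so "optimisation is easier with the spinal circuit" holds only
  marginally (medians within ~2 % at budget 100).

## A worked example

```{r example, eval = FALSE}
target <- make_target(baseline_flexion_extension_spec())
res <- optimise_supraspinal(target, with_minimal_sc = TRUE,
                            budget_iterations = 100, seed = 1)
cfg <- simulation_config(target = target, weights = minimal_sc_weights(),
                         commands = res$best_commands)
trace <- run_simulation(cfg)
metrics_report(trace, target)
```
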