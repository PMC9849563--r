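---
title: "Continuous gait-phase estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous gait-phase estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitphase)
```

## The estimation problem

A gait cycle runs from the heel strike of one leg (phase 0%) to the next
heel strike of the same leg (100%). Controllers for powered knee-ankle
prostheses and exoskeletons modulate joint impedance continuously, so they
need the instantaneous phase, not a retrospective one: knowing the phase
only after the stride has completed (as any event-to-event interpolation
must) is too late. `gaitphase` learns a direct regression from a short
history of four sensor channels — weight-normalized vertical load \(F_z\)
(body-weight units) and thigh/knee/ankle angles (degrees; extension,
flexion, dorsiflexion positive) — to the current phase. The channels were
chosen because essentially every powered lower-limb device measures them,
which is what makes the approach device-agnostic.

## Ground-truth labels from the vertical load

Training targets come from the load signal alone. A streaming segmenter
keeps a ring buffer of `lag = 8` smoothed load values, updated as
`influence * f_z + (1 - influence) * previous` with `influence = 0.01`, so
the buffer tracks a slow trend of the load. Each sample (clamped to
\([0, 1]\) BW) is labeled **stance** when it exceeds the hard threshold
`F_th = 0.2` BW, or when it is below the threshold but at or above the
buffer mean (load rising toward foot contact); it is **swing** when below
and falling, or when it exactly equals the buffer mean (the quiescent
unloaded state — both are zero during true swing). Equality is tested with
an absolute tolerance of 1e-9 because exact floating-point equality is
fragile; during genuine swing both sides are exactly zero, so the branch
behaves as intended. The buffer starts at all zeros (standing on the
contralateral leg); the first `lag` outputs simply use that initialization.

`F_th = 0.2` BW mirrors the stance-to-swing transition load used by
state-machine impedance controllers; `lag` and `influence` are the
peak-detector settings that proved robust on load traces. A persistence
pass then merges any label run of `p_hist = 5` samples or fewer (25 ms at
200 Hz) into its successor: such flickers are sensor interference, not gait.
The pseudocode formulation of this pass never writes the final run (the
commit happens only on a label *change*), so the implementation flushes the
trailing run with its own label at the end — the output must be fully
labeled. The merge keeps the segment start index, so consecutive short runs
fuse until something persistent arrives; the pass is idempotent.

Heel strikes are the swing-to-stance transitions of the refined labels. The
phase is taken **linear in time** between consecutive heel strikes — the
standard definition consistent with "0% at heel strike, 100% at the next" —
then quantized to the 0.5% grid (ties toward zero; 100% wraps to 0%, so
labels live on \(\{0, 0.5, \dots, 99.5\}\)). Samples before the first or
after the last heel strike have undefined phase and carry an `NA` sentinel;
they are excluded from training and evaluation.

## Polar encoding and scaling

The phase is cyclic, and a regression on raw percentages concentrates its
worst errors at the 100%/0% seam. The targets are therefore the unit-circle
coordinates \(\theta = 2\pi p_c / 100\),
\((p_x, p_y) = (\cos\theta, \sin\theta)\), scaled to
\(p' = (p + 5)/10 \in [0.4, 0.6]\). The inputs are scaled the same way,
\(v_n = (v / g_v + 5)/10\) with gain 1 for the load and 36 for angles. As
typeset, the scaling rule is ambiguous between multiplying and dividing by
the gain; both readings satisfy the load anchors (0 BW \(\to\) 0.5, 1 BW
\(\to\) 0.6, since \(g = 1\)), but only division keeps \(\pm 180^\circ\)
inside \([0, 1]\) with \(g = 36\), so division it is. The odd-looking
\([0.4, 0.6]\) output range is deliberate: it matches the data conventions
of the open-source leg's communication layer, so predictions can be
exchanged with the device without further conversion. Decoding inverts both
steps, \(p_c = (\operatorname{atan2}(p_y, p_x) \bmod 2\pi) \cdot 100/2\pi\);
network outputs need not lie exactly on the circle, and an output at the
circle center (radius below 1e-9 after unscaling) has no defined angle and
maps to the sentinel.

Errors are measured circularly, \(\min(|\Delta|, 100 - |\Delta|)\): an
actual phase of 99% predicted as 1% is a 2% error. Without the wraparound
minimum, boundary errors would explode and contradict the smooth
trajectories the predictor actually produces.

## The network

Input windows are the trailing 250 ms (50 samples at 200 Hz, stride 1
sample, target aligned to the **last** sample — causal, streaming-capable).
The architecture is conv1d (32 filters, kernel 8, stride 1, 'same' padding)
\(\to\) LSTM (20 units, consuming all 50 steps and emitting the last state)
\(\to\) dense 30 \(\to\) dense 10 \(\to\) dense 2, sigmoid on every
trainable layer. Parameter arithmetic pins down the hidden sizes: conv
\((8 \cdot 4 + 1) \cdot 32 = 1056\), LSTM
\(4 (32 + 20 + 1) \cdot 20 = 4240\), and only dense sizes 30 and 10 make
the total \(1056 + 4240 + 630 + 310 + 22 = 6258\) trainable parameters.
Sigmoid (rather than tanh/ReLU) suits the narrow near-0.5 operating range
of both inputs and outputs; in the LSTM it is applied as the candidate and
cell-output activation, with the usual sigmoid recurrent gates (parameter
count is unaffected either way).

Training: mean squared error on both outputs, Adam at learning rate 0.001,
15 epochs, batch 256, with a seeded 7:3 train/validation split. The split
is made **once** by default: re-splitting at every epoch (an option,
`resplit_each_epoch`) leaks validation windows into training across epochs
and overstates validation performance. Weights are Glorot-uniform with zero
biases and a unit forget-gate bias, seeded; the forward and backward passes
are hand-written compiled code (RcppArmadillo) and verified in the test
suite against a plain-R reference forward pass and against central-difference
gradients (max deviation ~1e-10 relative).

## The synthetic session generator

The public benchmark gait datasets cannot be shipped, so the generator
stands in for them with known ground truth. Each mode has a hand-designed
stride template: low-order Fourier joint-angle trajectories and a
stance-only load profile — for level-ground walking (LGW) the classic
double-bump (peaks ~1.1 BW at 22% and 78% of stance, mid-stance valley
~0.8 BW, stance fraction 0.60 of a 1.1 s stride), for stair ascent (SA) a
smoother single peak (stance fraction 0.65 of a 1.4 s stride). The load is
exactly zero in swing and rises steeply at heel strike (smoothstep over 2%
of stance), so ground-truth heel strikes coincide with load onset by
construction and the streaming segmenter recovers interior heel strikes
within ±3 samples. Strides are concatenated with per-stride duration jitter
(cadence CV 5%), per-stride amplitude scaling (CV 5%), and additive white
sensor noise (0.01 BW; 0.5° per angle) — values typical of treadmill
walking in healthy adults. `make_variant()` emulates the several-degree
discrepancies between motion-capture and goniometer measurements of the
same gait with a smooth per-channel offset process (bounded constant plus
slow sinusoidal wander) whose RMS follows the configured magnitudes
(defaults 6.2°/4.3°/3.7° for thigh/knee/ankle); `make_prosthesis_like()`
attenuates the stance-phase ankle excursion toward its per-stride stance
mean, emulating the too-flat ankle of an impedance-controlled prosthesis.

What the generator does **not** emulate: soft-tissue artifact spectra, true
inter-subject variability, turning, ramps, double-support asymmetries, or
any musculoskeletal dynamics. Passing tests on synthetic sessions therefore
demonstrate that the pipeline's machinery is correct and that the network
can learn the phase mapping from signals with realistic structure and
noise; they do not certify performance on any particular real sensor
system.

## Numerical and design choices

- **Resampling** to the 200 Hz working rate uses linear interpolation on a
  common time grid, both directions; gait signal content is far below
  Nyquist at these rates, so no anti-alias filter is applied. Constants are
  preserved exactly, band-limited components to within 1% amplitude.
- **Angular bias removal** subtracts per-channel constants, either supplied
  or estimated as the mean of a user-designated quiet-standing window.
- **Loads above 1 BW** are *not* clipped during scaling; clamping to
  \([0, 1]\) happens only inside the segmenter, which is where the
  algorithm specifies it.
- **Quantization ties** round toward zero, so a tie never advances the
  phase.
- **Session boundaries**: windows never straddle sessions (each session is
  windowed independently); incomplete strides at session edges keep the
  sentinel.
- **Reference problem sizes.** The end-to-end check trains on 300 LGW plus
  100 SA synthetic strides (~88,000 windows) and evaluates on held-out
  sessions (30 LGW + 15 SA, different seeds), requiring mean circular error
  below 5% and mean polar R² above 0.9. These sizes give a training set
  large enough for stable convergence of the 6,258-parameter network while
  keeping a full run to a few minutes on one core; the bar is deliberately
  conservative for a first-contact synthetic benchmark, and typical runs
  land near 1–2% error with R² above 0.98.

## Known limitations

- Only LGW and SA templates are provided; untrained modes (turning, ramps,
  descent) will degrade predictions, as any learned phase estimator does.
- The segmenter assumes a load signal that is near zero in swing; heavily
  drifting or unweighted-limb data will confuse the rising-load heuristic.
- The first `window - 1` samples of a session have no prediction (no full
  history), and phase outside complete strides is undefined by
  construction.
- Training is CPU-only and single-threaded beyond BLAS; the model is tiny,
  which is the point — it fits the latency budget of an embedded
  controller.
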