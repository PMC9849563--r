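# gaitphase

Continuous gait-phase estimation from the sensor channels commonly available
on powered lower-limb assistive devices: weight-normalized vertical load and
thigh, knee and ankle angles.

## The problem

Controllers for powered prostheses and exoskeletons need to know *where in
the gait cycle* the user currently is — not just a discrete stance/swing
state, but a continuous phase from 0% (heel strike) to 100% (the next heel
strike of the same leg). Discrete event detectors can only report the phase
in hindsight, once a full stride has been observed; a controller needs it
now. `gaitphase` implements a device-agnostic pipeline that learns the
mapping from a short sensor history to the instantaneous phase:

1. **Segmentation.** A streaming peak-detection scheme on the vertical load
   `F_z` (smoothed ring buffer of `lag = 8` values, update weight
   `influence = 0.01`) labels each 200 Hz sample stance or swing: stance
   whenever `F_z > F_th = 0.2` BW, or when `F_z` is rising relative to the
   smoothed trend; label runs of `p_hist = 5` samples or fewer (25 ms) are
   merged away as sensor interference.
2. **Phase labels.** Heel strikes are the swing-to-stance transitions. The
   phase `p_c` is linear in time between consecutive heel strikes, quantized
   to 0.5%, and encoded on the unit circle to remove the 100% to 0% wrap:
   `theta = 2*pi*p_c/100`, `(p_x, p_y) = (cos theta, sin theta)`, then
   scaled to `p' = (p + 5)/10` in `[0.4, 0.6]`. Inputs are scaled the same
   way, `v_n = (v/g_v + 5)/10`, with gain 1 for the load (0 BW maps to 0.5,
   1 BW to 0.6) and 36 for the angles.
3. **Model.** A small conv-LSTM network — conv1d (32 filters, kernel 8,
   stride 1, 'same' padding) -> LSTM (20 units) -> dense 30 -> 10 -> 2,
   sigmoid activations throughout, exactly **6,258 trainable parameters** —
   maps the 250 ms history (50 samples x 4 channels) to `(p'_x, p'_y)`.
   Trained 15 epochs with Adam (lr 0.001), batch 256, MSE loss, 7:3
   train/validation split. The forward/backward passes are compiled
   (RcppArmadillo); training the reference problem takes a few minutes on
   one CPU core.
4. **Evaluation.** R² per scaled polar component, circular phase error
   `min(|d|, 100 - |d|)`, and Pearson correlations between median stride
   trajectories (strides time-normalized to 101 phase points).

Because the public benchmark gait datasets cannot be redistributed, the
package ships a synthetic session generator (`generate_session()`) with
mode-specific stride templates (level-ground walking and stair ascent),
double-bump stance load, cadence/amplitude variability, sensor noise, and
known ground-truth heel strikes and phase — so the whole pipeline is
testable end to end, including sensor-configuration variants
(`make_variant()`) and prosthesis-like flattened ankle trajectories
(`make_prosthesis_like()`).

## Worked example

```r
library(gaitphase)

train <- generate_session("LGW", 100, seed = 11)
fit   <- gaitphase_fit(train$series, train$phase,
                       gaitphase_config(epochs = 15, seed = 1))
test  <- generate_session("LGW", 20, seed = 99)
pred  <- predict(fit, test$series)
evaluate_predictions(test$phase, pred)
```

```
<gait_eval>
  n samples      : 4279
  R2 (px, py)    : 0.9972, 0.9969  (mean 0.9970)
  circular error : mean 0.70%, median 0.59% [IQR 0.28-1.02]
```

Read: on a held-out synthetic walking session the predicted phase tracks the
true phase to better than one percent of the gait cycle, and the two polar
components are essentially fully explained (R² near 1). `summary(fit)`,
`plot(fit, "loss")` and `residuals(fit)` give training curves and held-out
residual diagnostics; `coef(fit)` returns the layer weight matrices.

The same pipeline is scriptable from the shell via `exec/gaitphase`:

```sh
Rscript exec/gaitphase simulate --seed 1 --out runs/demo
Rscript exec/gaitphase segment  --input runs/demo/session.csv
Rscript exec/gaitphase label    --input runs/demo/session.csv
Rscript exec/gaitphase train    --input runs/demo/session.csv --out runs/demo
Rscript exec/gaitphase predict  --input runs/demo/session.csv --model runs/demo/model.json
Rscript exec/gaitphase evaluate --input runs/demo/session.csv --out runs/demo
```

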