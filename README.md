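# tactomyo

Proportional, simultaneous myocontrol from **tactile myography**
(high-density force myography): an R toolkit for decoding intended hand and
wrist actions from a 288-taxel forearm bracelet, with a synthetic bracelet
simulator and a Target Achievement Control (TAC) test engine.

## Who this is for

Researchers in neuroprosthetics and biosignal processing who want a tested,
hardware-free implementation of the tactile-myography decoding pipeline:
to study how a linear decoder trained on *single* actions generalizes to
*combined* actions (e.g. power grasp while pronating), how feature
reduction and sensor non-idealities (noise, drift, saturation) affect that
generalization, and how TAC-style closed-loop experiments behave under
controlled, reproducible conditions.

## The model

A bracelet frame is a 9 × 8 × 4 grid of normalized force readings
`x ∈ [0,1]^288`, sampled at 100 Hz and low-pass filtered (causal
first-order Butterworth, 1 Hz). Intent detection is ridge regression: given
m training pairs `X ∈ R^{m×D}`, `Y ∈ R^{m×d}`,

    W = (XᵀX + λI)⁻¹ XᵀY,        ŷ = Wᵀx̂  (clamped to [0,1]),

with λ = 1 and d = 6 activation channels (rest, power, flexion, extension,
pronation, supination). Two feature pipelines feed it:

* **RR** — the 288 filtered taxels, unchanged (D = 288);
* **RR-ROIG** — each board split into two 4 × 4 regions of interest
  (18 ROIs tiling all taxels), each summarized by a ridge-penalized plane
  fit `Ĝ(x,y) = α(x−x₀) + β(y−y₀) + γ`, i.e. `w = (AᵀA+λI)⁻¹Aᵀr`,
  giving D = 54 — one sixth of the input at similar decoding quality.

Feasible combined-action targets come from the biomechanics of grasping: an
embedded 12-study table of maximal grip strength (% of neutral MVC) per
forearm × wrist posture is averaged per condition and alleviated by a
factor of 0.8 to produce per-activation limits (e.g. power while flexing:
0.66 × 0.8 = 0.528). The TAC engine then scores closed-loop trials —
15 s timeout, 1.5 s dwell within an absolute 0.2 tolerance on every target
activation — reporting success rate (SR), time to complete task (TCT,
successful trials only), cumulative time in target (TIT) and reachability.

The simulator renders frames as baseline plus an activation-weighted
**linear superposition** of per-action muscle-bulge templates, passed
through a sensor model (compressive saturating response, per-taxel noise,
slow drift), plus a proportional-controller subject — enough to exercise
the whole pipeline end to end and to show both superposition recovery and
its breakdown under power-grasp saturation.

## Worked example

```r
library(tactomyo)

templates <- action_templates()
sensor    <- sensor_model(noise_sd = 0.01, seed = 42)

# ~2 min synthetic recording: 6 stimulated channels x 3 repetitions
session <- generate_training_session(templates, sensor)
#> <training_session> 18 bouts, 12800 samples @ 100 Hz

# reduced-feature decoder: filter -> 54-dim ROI gradients -> ridge
decoder <- train_decoder(session, method = "roig", lambda = 1)
#> <ridge_model> roig features, D = 54 -> d = 6, lambda = 1, m = 12800

# a combined target bounded by the grip-strength table:
# power while pronating is limited to 87% MVC x 0.8 = 0.696
target <- target_spec("power+pronation",
                      c(power = derive_limit(87, 0.8), pronation = 0.8),
                      "combined-with-power")
trial <- run_trial(decoder, subject_model(), target, templates, sensor,
                   trial_config(), seed = 42,
                   t0 = max(session$stream$time) + 1)
trial
#> <trial_result> power+pronation [combined-with-power, roig]: success; tct = 1.83 s, tit = 1.50 s
```

The decoder was trained on single actions only, yet the combined
power + pronation target is reached and held for the full 1.5 s dwell
0.33 s after the loop settles — the superposition property at work. The
grip table itself:

```r
condition_mean(grip_strength_table(), "neutral", "flexion")$rounded
#> [1] 66
derive_limit(66, 0.8)
#> [1] 0.528
```

`run_session()` runs the full protocol (3 task-reaching phases × 13 tasks
× 2 methods, retraining between phases) and aggregates SR/TCT/TIT per
method and task group; `cmd_*()`/`exec/tactomyo` expose the same steps as
a command line (`simulate`, `train`, `predict`, `tac`, `limits`,
`report`).

## Package layout

* `R/tactile-stream.R` — frame/stream data model, CSV I/O, causal
  Butterworth filtering (stateful 288-channel stepper for online loops)
* `R/features.R` — raw and ROI-gradient feature pipelines
* `R/regression.R` — closed-form ridge decoder, retraining, serialization
* `R/biomechanics.R` — grip-strength table, condition means, activation
  limits, task-set construction
* `R/simulator.R` — action templates, sensor and subject models, training
  session generator
* `R/tac.R` — trial/session engine and report aggregation
* `R/cli.R`, `exec/tactomyo` — command-line entry points
* `vignettes/tactile-myocontrol.Rmd` — the methods vignette: models,
  parameter choices, numerical conventions, and limitations
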