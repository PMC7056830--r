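---
title: "Tactile myography myocontrol: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tactile myography myocontrol: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactomyo)
```

## The problem

Tactile myography (high-density force myography) senses voluntary muscle
activity through the pressure that bulging forearm muscles exert on a dense
bracelet of force cells ("taxels"). Each intended hand or wrist action
produces a repeatable spatial pressure pattern, so a simple linear decoder
can map a 288-taxel reading to graded activation levels for six channels:
rest, power grasp, wrist flexion, wrist extension, pronation and
supination. The interesting question is *combined* actions: can a decoder
trained only on single actions (grasp alone, flexion alone, ...) decode a
simultaneous grasp-while-pronating? If pressure patterns superpose roughly
linearly in the input space, a linear decoder gets combined actions for
free, which matters because collecting training data for every combination
is impractical for a prosthesis user.

`tactomyo` implements that full pipeline — data model, filtering, two
feature pipelines, ridge decoding, biomechanics-derived target limits, a
Target Achievement Control (TAC) test engine — together with a synthetic
bracelet simulator built on the superposition hypothesis, so that every
stage can be exercised and tested end to end without hardware.

## Data model and filtering

A frame is a 9 (boards) × 8 (rows) × 4 (columns) grid of readings
normalized to [0, 1], flattened board-major, then row, then column; streams
are sampled at 100 Hz. The flattening order is arbitrary in principle
(regression is permutation invariant) but normative here, because the
region-of-interest partition below depends on it.

All features are computed from a causally low-pass filtered signal: a
first-order digital Butterworth filter with 1 Hz cut-off, designed by the
bilinear transform and applied in a single forward pass per taxel. There is
no zero-phase (forward–backward) filtering anywhere: the decoder runs
online and must remain causal. Two numerical choices are worth noting:

* **State priming.** The recursion starts at the steady state for the first
  sample value, so a recording that begins at rest shows no start-up
  transient. This mimics a continuously running online system.
* **Clamping at the type boundary only.** The internal filter state is
  exactly linear (a property the test suite checks to 1e-9); outputs are
  clamped to [0, 1] only when a stream object is rebuilt.

The discrete step response of the bilinear design reaches ≈ 0.6435 one
analog time constant (1/2π s) after the step onset, within 2 % of the
continuous first-order value 1 − e⁻¹ ≈ 0.6321; the time constant falls
between two 100 Hz samples, so comparisons interpolate the sampled output
at t = τ rather than snapping to the nearest sample, which would add a
half-sample phase artifact of about the same size as the discretization
error itself.

The sensor's compressive nonlinearity is deliberately *not* inverted
anywhere in the pipeline: linearization would cost computation and reshape
the noise, and the decoder is trained on the same nonlinear readings it
sees at run time.

## Feature pipelines

Two pipelines feed the decoder:

* **Raw (RR):** the 288 filtered taxels, unchanged.
* **ROI gradients (RR-ROIG):** each board is split into two non-overlapping
  4 × 4 squares — 18 regions tiling the 288 taxels exactly once — and each
  region is summarized by a first-order plane fit
  Ĝ(x, y) = α(x − x₀) + β(y − y₀) + γ, giving a 54-dimensional vector,
  one sixth of the raw dimensionality. α and β are the mean gradients along
  the two axes; γ is the plane's offset.

The plane coefficients solve the ridge-penalized least squares
w = (AᵀA + λI)⁻¹Aᵀr over the 16 taxels of the region, with the patch
flattened row-major and local coordinates measured from the region's
upper-left corner. Two conventions deserve explanation:

* **All three coefficients are penalized**, including the offset γ, exactly
  as the closed form above is written. The default penalty is λ = 1, the
  same standard value used for the decoder itself; λ = 0 recovers the plain
  least-squares plane and is what the oracle tests compare against.
* **Corner-anchored γ.** With corner-anchored coordinates, γ is the fitted
  plane's value at the region's interest point, *not* the patch mean. The
  two readings coincide only under patch-centered coordinates, which are
  available via `centered = TRUE` for anyone preferring a mean-gray-value
  interpretation of γ; the corner convention is the default because the
  interest point of each region is defined at its upper-left corner.

Because the penalized fit is linear in the patch, the entire 54-dim
extraction is one fixed 54 × 288 matrix (`roig_transform()`), which is how
long recordings are featurized efficiently; per-frame extraction and the
linear map agree to 1e-12 by test.

## Ridge decoding

Training solves W = (XᵀX + λI)⁻¹XᵀY in closed form with λ = 1 by default;
prediction is ŷ = Wᵀx, clamped to [0, 1] per activation only after the
linear map. There is no intercept column and no feature standardization —
the closed form is applied exactly as written, which has a practical
consequence: the rest posture must be representable. That is handled by the
label model, below. Retraining (to counter drift) defaults to *replace* —
fresh signals supersede stale ones, which is the reason retraining exists —
with *append* retained for experiments via stored sufficient statistics.

**Label construction.** During a stimulated bout the trained action's label
follows the trapezoidal stimulus profile (0 → 1 → 0). Rest is a sixth
output channel whose label is the complement of the stimulated level: fully
active at rest, fading as an action engages. Six trained channels including
rest match the experimental configuration this package models, and the
complement encoding makes a noiseless single-action training set exactly
linearly consistent — the decoder can satisfy Wᵀ(baseline) = e_rest and
Wᵀ(pattern_k) = e_k − e_rest simultaneously, which is precisely what the
superposition-recovery property requires. A `rest = FALSE` switch drops the
channel (d = 5) for ablation.

## Biomechanics of grasping: feasible combined targets

The grip strength a posture permits varies strongly with wrist and forearm
position (tenodesis, length–tension of the extrinsic finger muscles). The
package embeds a twelve-study literature table of maximal grip strength as
a percentage of the neutral-posture MVC for each forearm (pronation /
neutral / supination) × wrist (extension / neutral / flexion) condition,
and reproduces its per-condition mean over the studies that report each
cell. One printed cell is inconsistent: the pronation + flexion column
averages to 56.33 from the printed study values, while the printed summary
row shows 57. The recomputed value is what `condition_mean()` returns; the
exact-value tests cover the other eight conditions, and the discrepancy is
documented here rather than silently patched in the data.

Feasible target levels are `mean% / 100 × 0.8`, the alleviating factor of
80 % applied exactly once to leave a safety margin below the physiological
extreme. Wrist-only combinations have no literature table; their default
level of 0.8 per involved activation is *configured*, and tagged as such in
`activation_limits()`, never presented as table-derived. The default task
set is 13 tasks — 5 singles, 4 wrist-only pairs (non-antagonistic), 4
power pairs — with power levels bound by the matching posture condition.
Ulnar/radial deviation is excluded throughout.

## The synthetic bracelet

The simulator generates everything the pipeline consumes:

* **Templates.** Each motor action is a smooth unit-peak Gaussian bump on
  the unrolled 8 × 36 taxel sheet (wrap-around along the 36-position
  circumference), centered at an action-specific circumferential position.
  True bulge statistics are not published, so the templates are stylized;
  every acceptance property tied to them is structural (recovery, ordering,
  determinism), never a claim about real-data numbers. The power-grasp
  template is broad (σ ≈ 7 positions vs 3 for wrist actions) and overlaps
  the flexion support, emulating the shared extrinsic muscles; its gain
  (0.8 vs 0.5) makes grasping the dominant pressure source, so that power
  combinations are the first to push taxels toward saturation.
* **Superposition.** Rendered pressure is baseline plus the
  activation-weighted sum of templates. With the linear response the
  default gains keep every feasible task below the sensor ceiling, so the
  input space is exactly linear there — the regime in which a λ→0 decoder
  trained on singles recovers combined levels to 1e-6 (measured ≈ 2e-9).
* **Sensor response.** Either linear or compressive,
  baseline + (1 − baseline)(1 − e^{−gp})/(1 − e^{−g}) with g = 3, a
  monotone saturating curve of the qualitative shape measured for
  conductive-foam taxels. Saturation is what breaks superposition for
  power-grasp combinations: under the compressive response the mean
  absolute decoding error of power-combined targets is ~2.6× the error of
  wrist-only combinations under matched seeds, reproducing the observed
  group ordering (power-combined worst) qualitatively.
* **Noise, drift, hysteresis.** Per-taxel Gaussian noise is seeded per
  frame from the sensor seed and the timestamp, so any frame is
  reproducible in isolation; per-taxel linear drift slopes (the simplest
  model that makes retraining necessary) are drawn once from the sensor
  seed; loading/unloading hysteresis is available but off by default.
* **Subject.** A proportional controller: intended activation moves by
  gain × (target − feedback) per 10 ms step, optionally with motor noise, a
  reaction delay, or a sequential strategy that ramps one action of a
  combination at a time (holding later actions at zero until the earlier
  ones are within a band). The default gain of 0.05 per step (5 s⁻¹)
  settles in roughly a second against the 1 Hz-filtered plant without
  oscillating; gains an order of magnitude higher interact with the filter
  lag and ring.

## The TAC engine

A trial succeeds at the first completion of ⌈dwell × fs⌉ consecutive
in-target samples (150 at the defaults: 1.5 s dwell, 100 Hz) within a 15 s
timeout. "In target" means *every* activation named by the target —
including those required to stay at zero — is within an absolute tolerance
(0.2; 0.25 as the relaxed variant) of its target level. Conventions that
were genuinely open and are now fixed:

* **Absolute tolerance** on the normalized scale, not relative to the
  target level: a relative band would make near-zero targets unreachable
  and leaves required-zero activations undefined.
* **Closed boundary** (error = tolerance counts as in-target), implemented
  with a 1e-12 epsilon so that, e.g., |0.8 − 0.6| compares as ≤ 0.2
  despite floating point.
* **Uninvolved activations are held to zero** within the same tolerance;
  the decoder's rest channel is excluded from the check by default
  (`include_rest` enables the stricter variant), since rest is a
  complement-coded display channel rather than a target dimension — for a
  single 0.8-level target it sits exactly on the tolerance boundary, where
  sensor noise would make success a coin flip on a channel the task never
  specified.
* **TCT** is the time from stimulus onset to the dwell-completing sample;
  TCT statistics aggregate over successful trials only, TIT is reported
  split by success/failure, and *reachability* records whether the band was
  entered for at least one sample.

A session is an initial training recording, then repeated task-reaching
phases (3 by default) with a fresh two-repetition training recording before
each later phase — retraining that counters the accumulated sensor drift.
Each phase presents all 13 tasks once per feature method, alternating
between the methods in a seeded random order. The session clock runs
through recordings, trials and inter-trial gaps so drift accrues
realistically.

## Problem sizes, determinism, and what the tests show

The default synthetic conditions are: a ~2 min training recording (6
stimulated channels × 3 repetitions, 7 s bouts), λ = 1, 1 Hz first-order
filtering, sensor noise σ = 0.01 for closed-loop runs (σ = 0.005 for
open-loop error measurements), baseline 0.05, drift off unless the
property under study is drift itself. Unit tests use shortened recordings
(0.5–2 s bout phases) where only structure matters. All randomness flows
from explicit seeds — sensor noise per frame, drift slopes at sensor
construction, task order per phase, subject noise per trial — and matched
seeds reproduce streams bit for bit.

What passing tests do and do not establish: the suite demonstrates the
*mechanism* — exact closed-form solvers (checked against independent
least-squares, pseudo-inverse and gradient-descent oracles), exact protocol
arithmetic, superposition recovery when the input space is linear, and its
qualitative breakdown under saturation. It does not establish human success
rates: real subjects contribute motor learning, fatigue, socket fit and
bulge statistics no stylized template reproduces, so no number produced by
the simulator should be read as a prediction of human TAC performance.

## Known limitations

* Templates are stylized Gaussians; real bulge patterns are not published.
* Drift is linear per taxel; real foam drift is nonlinear and
  history-dependent (the hysteresis option is a crude stand-in).
* The simulated subject is a proportional controller with no learning
  across phases, so session-to-session improvement effects are absent.
* Append-mode retraining requires the in-memory model; serialized JSON
  models support replace mode only.
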