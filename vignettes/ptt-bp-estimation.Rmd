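---
title: "Compensated PTT-based blood pressure estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compensated PTT-based blood pressure estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pttbp)
```

## The estimation model

Pulse transit time (PTT) is measured per beat as the interval from the ECG
R-peak to the PPG pulse peak of the same cardiac cycle. The classical
cuffless estimator is the linear map `BP = a·PTT + b`; it works tolerably
for systolic pressure (SBP), which is strongly coupled to pulse wave
velocity, but poorly for diastolic pressure (DBP). `pttbp` estimates

```
BP = a·PTT + b + c·VPTT + d·(PTTV − PTTV₀)
```

per beat, where PTT is the mean of the past `W = 5` per-beat transit
times, `VPTT = (PTT − PTT₀)/PTT₀` is the relative variation from the
sitting-calibration reference, and PTTV is the variability of the window —
a surrogate for autonomic (neural) vasomotor regulation, which modulates
DBP with little PTT-level signature. Both compensation terms vanish at the
sitting calibration state by construction, so the compensated and linear
models coincide there and differ exactly where regulation-state changes
occur.

Assumptions worth making explicit:

- the subject's PTT–BP relation is locally linear over the measured range;
- the sitting calibration session is representative (its mean PTT and mean
  rolling PTTV define `PTT₀` and `PTTV₀`);
- a window of 5 beats is short enough to track beat-scale changes yet long
  enough for a meaningful dispersion estimate;
- SBP and DBP carry fully independent coefficient sets.

### The PTTV convention

The variability of a window is defined as the **sample standard deviation
of the successive PTT differences**. A window of `W = 5` PTT values yields
4 differences, hence denominator 3. The phrase "N is the number of PTT
values" admits a second reading — N differences drawn from N + 1 values —
which is selectable via `run_config(pttv_convention = "n_differences")`;
the default honours the statement that each estimate uses the past five
measurements. PTTV is invariant under adding a constant to the window and
is exactly zero for any arithmetic PTT progression, both covered by tests.

### Units

PTT is in ms everywhere, so `a` and `d` are mmHg/ms, `b` is mmHg and `c`
is mmHg (it multiplies the dimensionless VPTT). Fixing ms end-to-end
avoids silent 1000× coefficient errors.

## Signal processing

- **Smoothing.** A centred moving average of 10 ms; at 250 Hz that is 2.5
  samples, rounded to the nearest odd window (3 samples) so the filter has
  no phase shift. Edges shrink the window symmetrically; a sub-sample
  duration degenerates to the identity.
- **R-peak detection.** A simplified Pan–Tompkins scheme: smoothed
  derivative-squared energy integrated over 120 ms, an adaptive threshold
  (median + 3·MAD, with a small relative floor that absorbs floating-point
  dust on silent stretches), candidate reduction to the local maximum of
  the smoothed ECG, an amplitude screen at 40% of the median candidate
  amplitude, and a 250 ms refractory period that keeps the taller of any
  conflicting pair.
- **PPG pulse pairing.** Within each R–R interval the pulse peak is the
  argmax of the smoothed PPG inside the physiologic transit window
  (100–600 ms after the R-peak, truncated at the next R-peak). The argmax
  is accepted only as an interior local maximum — a maximum sitting on the
  window boundary means the true peak lies outside the physiologic window
  and the cycle stays unmatched. Ties take the earliest sample. The last
  R-peak of a recording opens no complete cycle, so a session of B beats
  yields at most B − 1 PTT values.
- **Data rejection.** A session is invalid when the PTT coefficient of
  variation exceeds 0.2, when more than 20% of cycles are unmatched, or
  when fewer than 10 beats are available. The thresholds are configurable;
  the defaults were chosen once as conservative screens for "large
  fluctuation" and are exercised by a generator mode that injects a
  measurement-artifact burst.

## Calibration

Stage one regresses resolved reference pressure on
`[PTT, 1, VPTT, PTTV − PTTV₀]` by ordinary least squares over pooled
subject–session points — one point per session, because the oscillometric
cuff yields a single reference per session (per-beat pooling with repeated
references is available for simulation work). The fitted `c` and `d` are
retained as population constants. By default the pipeline fits them
leave-one-subject-out, so a subject's own sessions never inform their
compensation constants; `population_fit_scope = "pooled"` reproduces the
all-data design.

Stage two solves the 2×2 system given by the sitting and standing
calibration sessions with `c`, `d` fixed. Because the sitting session
defines `PTT₀` and `PTTV₀`, its compensation terms are identically zero
and the fitted line interpolates the sitting point exactly — a property
the tests assert to machine precision. Postures whose mean PTT differs by
less than 2 ms (half the 4 ms sample period at 250 Hz) make the system
ill-conditioned and raise a degenerate-calibration error rather than a
silent bad profile.

The measurement-acceptance rule for the cuff reference partitions the
difference between the first two readings without gaps: `< 5` mmHg keeps
the first reading, `5–10` mmHg (both boundaries included) requires a third
reading and uses the mean of three, `> 10` mmHg discards the session. The
rule is applied to SBP and DBP independently, and a session is discarded
if either type is discarded (the conservative joint reading).

## The synthetic cohort generator

No recorded cohort ships with the package, so the generator defines the
study conditions: it emulates what the estimation model assumes about
physiology and lets every pipeline stage be tested against known truth.

Per subject it draws a law — true coefficient sets for SBP and DBP, a
baseline PTT, a heart rate — and produces three sessions. Beat times
follow the heart rate with 3% interval jitter. Per-beat PTT is baseline +
posture shift + a sinusoidal low-frequency oscillation (Mayer-wave band) +
white jitter, **quantized to the sampling grid**: the truth is defined on
the grid the waveforms are rendered on, so noise-free peak detection can
recover it exactly and end-to-end inversion is limited only by
quantization. Per-beat BP follows the subject's own compensated law,
evaluated with the same rolling-window code the estimation pipeline uses.
The session-level "true" BP applies the law to the session feature
summary, which makes the sitting compensation terms exactly zero and
noise-free calibration recovery exact. The last beat of each session is
flagged non-measurable (no closing R-wave), and all session summaries run
over measurable beats only.

Defaults, chosen once as plausible for healthy young adults and then
frozen:

| parameter | default | note |
|---|---|---|
| sessions | 3 × 180 s at 250 Hz | sitting / standing calibration + sitting test |
| baseline PTT | N(200, 45) ms, clipped 130–320 | between-subject spread |
| posture shift | −15 ms standing | hydrostatic effect |
| LF oscillation | 5 ms amplitude, 10 s period | Mayer-wave band; ×1.4 standing |
| beat PTT jitter | 2 ms | white |
| heart rate | N(70, 8) bpm, clipped 50–100 | |
| SBP law | a = −0.45, c = −40, d = 0.8; resting SBP N(115, 8) | |
| DBP law | a = −0.15, c = −60, d = 3.5; resting DBP N(72, 6) | |
| test-session drift | PTT offset N(0, 8) ms; LF/jitter scale lognormal(0, 0.35) | state change between calibration and test |
| per-beat BP noise | 2 mmHg | |
| oscillometer noise | 2 mmHg per reading | drives the protocol branches |
| waveform noise | ECG 0.02, PPG 0.002 (unit peaks) | |

Two design points deserve comment.

*Identifiability.* Within one subject, VPTT is an exact affine function of
PTT, so `a` and `c` are separable only through between-subject spread in
`PTT₀` — an a-priori standard-error calculation, not a tuning run, drove
the baseline spread (SD 45 ms) and the session-to-session test drift,
without which `c` is practically unidentifiable from session-level data.
The same calculation shows that with one noisy cuff reference per session
(90 points) the precision on `c` is poor; the parameter-recovery test
under per-beat BP noise therefore pools per-beat truth rows, which is the
regression's statistical behaviour test, while the pipeline itself always
uses the honest session-level design.

*Coupling strength.* `d` is deliberately smaller for SBP than for DBP:
the variability term encodes vasomotor regulation, which is the dominant
unexplained component of DBP but a minor one of SBP. This is what makes
the compensated and linear models comparable on SBP while the compensated
model dominates on DBP — the qualitative pattern the evaluation tests
assert over 20 seeded replicate cohorts.

What the generator does **not** emulate: realistic QRS/PPG morphology
(waves are Gaussian and raised-cosine bumps with single unambiguous
maxima), dicrotic notches, baseline wander, motion artifacts, respiratory
modulation, or nonlinear PTT–BP relations. Passing tests therefore show
that the pipeline correctly inverts data satisfying the model's own
assumptions — they do not certify accuracy on recorded clinical signals.

## Numerical choices

- Sample indexing: sample *k* (0-based) is at time *k/fs*; in R's 1-based
  storage, index *i* is at *(i − 1)/fs*. PTT differences are index
  differences over *fs*, so the convention cancels.
- Argmax ties take the earliest sample (determinism).
- The moving-average filter uses a cumulative-sum formulation; the R-peak
  energy threshold has a `1e-9 · max` relative floor so exact-zero
  stretches do not trigger on accumulated rounding dust.
- Waveform CSVs are written with 17 significant digits and parsed with
  correctly-rounded base conversion, so disk round trips are bit-exact.
- Bland–Altman SD uses the sample (n − 1) denominator; limits are
  mean ± 1.96 SD. Degenerate reports (n = 1, zero variance) are emitted
  with the undefined fields flagged rather than erroring the whole run.

## Problem sizes in the test suite

Unit tests use 1–4 subjects at 40–60 s per session. The property suite
uses: 10 subjects (noise-free detection exactness), 30 subjects × 60 s
(noisy-detection match rate; noise-free coefficient recovery at 1e-6),
30 subjects × 120 s of truth rows (noisy `c`, `d` recovery within 10%),
and 20 replicate cohorts of 10 subjects × 60 s (compensated-vs-linear
comparison). The acceptance script runs the full default conditions:
30 subjects × 3 × 180 s. These sizes were fixed as the package's standard
experiment scales.

## Known limitations

- The R-peak detector targets the generator's clean morphology plus white
  noise; it is not a validated clinical QRS detector.
- PTT here is R-peak-to-pulse-peak (it includes the pre-ejection period);
  foot-based or second-derivative fiducials are out of scope.
- Coefficients are assumed stable over a session; longitudinal drift and
  recalibration scheduling are not modelled.
- Only sitting/standing hydrostatic calibration is implemented; exercise
  or cold-pressor perturbations are not.
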