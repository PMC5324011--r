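---
title: "The two-channel EMG controllability battery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-channel EMG controllability battery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoassess)
```

## The measurement problem

Two-channel myoelectric control — one surface electrode over the wrist
flexors, one over the extensors — is the standard input scheme for
transradial prostheses. Training and assessing that control requires a
battery of tasks that quantify, per participant and session, how well
the two muscle channels can be (i) calibrated, (ii) driven to a
prescribed intensity, (iii) activated separately rather than together,
and (iv) sustained against a slowly moving target. `myoassess`
implements that battery for envelope-level recordings: each electrode is
assumed to deliver a non-negative RMS envelope at 100 Hz, with all
filtering and rectification done upstream in hardware. Raw EMG never
enters the package.

Because the hardware amplification is arbitrary, no score ever uses the
volt scale directly. Everything is expressed relative to the maximum
voluntary contraction (MVC) of the corresponding channel, which the
calibration step estimates per session.

## The four assessments

**MVC calibration.** The participant maximally contracts one muscle and
holds it for 1.3 s; only the final 1.0 s of the trial enters the
activation baseline (the onset transient is excluded), and the MVC is
the mean of three such trials per channel. The MVC is provisional —
later contractions may exceed it — so normalized values above 1 are
allowed and never clipped.

**Precision control.** For each electrode the participant reaches 30
goal activation levels (3 trials × 10 levels) drawn uniformly from
10–90 % MVC, each held for 300 ms. The randomization is performed once,
fixed by `schedule_seed`, and reused for every participant and session,
so between-subject and between-session differences are never
confounded with different schedules. The achieved level of a mark is
the *mean* normalized activation over its 300 ms hold window — the mean
matches the "sustain" instruction and is robust to envelope noise,
where an endpoint reading would not be — and the outcome is the
absolute deviation from the goal in percent MVC. Goals are divided into
three equidistant intensity bands (low/middle/high, width 80/3 % MVC
each); band intervals are half-open on the left with boundary ties
assigned upward, an arbitrary but fixed convention.

**Electrode separation.** During each precision mark, the *opposing*
electrode is compared against an activation threshold of 15 % of its
MVC — the same bar that would trigger a prosthetic movement. A mark
fails separation if **any** sample of the opposing channel inside the
hold window reaches the threshold. The any-sample criterion (rather
than a window mean) reflects how a threshold-triggered device behaves:
a single crossing would actuate it. The outcome is the percentage of
marks with opposing activation, overall and per intensity band.

**Endurance control.** The participant retraces a 1/4 Hz sine whose
peaks correspond to 60 % MVC, using the signed bipolar composite
$x(t) = \hat{e}_1(t) - \hat{e}_2(t)$ of the two normalized channels
(flexion positive, extension negative). Conformity is scored in
consecutive non-overlapping 30 s windows as

$$ r^2_w = \max\!\left(0,\; 1 - \frac{\sum_{t \in w} (x_t - s_t)^2}
   {\sum_{t \in w} (s_t - \bar{s}_w)^2}\right), $$

the coefficient of determination of the composite *against the
reference* $s(t) = 0.6 \sin(2\pi t/4)$, floored at zero. This is a
deliberate choice over squared Pearson correlation: a participant
tracking in perfect antiphase has Pearson $r^2 = 1$ but is doing the
task exactly wrong; the deviation-based definition scores that
performance 0, matching how such an outlier should rank. The headline
score `best_r2` is the maximum, over all contiguous runs of windows
spanning at least 200 s (seven 30 s windows), of the mean window score.
The phrase "highest score from a period of at least 200 s" is ambiguous
between *best single window inside ≥ 200 s of data* and *best aggregate
over a ≥ 200 s span*; the aggregate reading was chosen because a single
30 s window cannot measure endurance, and the run-mean is the natural
span statistic. Recordings shorter than 200 s yield window scores but
no `best_r2` (with a warning); the default minimum session length is
300 s, configurable via `min_session_s`.

## Game control mapping

The games substitute keyboard events with EMG activation. Each
normalized channel passes through a hysteresis detector: an interval
opens at 15 % MVC and closes below 10 % MVC. The two thresholds prevent
chatter when the envelope hovers at the activation bar; the off
threshold sits at two-thirds of the on threshold, a conventional
hysteresis ratio. Intervals lasting at most 300 ms are *quick*, longer
ones *sustained*. A *cocontraction* — quick contractions on both
channels with onsets within 100 ms — cycles the active degree of
freedom forward (horizontal → vertical → horizontal with two DoFs) and
suppresses the key events of the participating intervals. Both
intervals must be quick: a sustained bilateral press is intentional
simultaneous control, which the rhythm game requires, and is exposed
via `cocontraction_mode = "chord"` where cocontractions are not
resolved at all. All other intervals emit a press at onset and a
release at offset of the key the active DoF assigns to their channel;
a release always uses its press's key even if the DoF changes while a
key is held. The mapping is a pure function of (recording, calibration,
config). Proportional control and OS-level key injection are out of
scope — the games consume discrete key events.

## The synthetic participant

Human recordings are replaced by a generative model with seven
interpretable parameters, each chosen to be the simplest mechanism the
battery's scores are sensitive to:

| parameter | unit | default | role |
|---|---|---|---|
| `mvc_true` | V | 2.0 / 1.8 | true per-channel MVC; arbitrary scale |
| `idle_offset` | MVC fraction | 0.02 | resting envelope floor (common noise) |
| `noise_sd` | MVC fraction | 0.04 | Gaussian envelope noise, clipped at 0 |
| `bias` | MVC fraction | 0.02 | systematic over/undershoot of goals |
| `lag_s` | s | 0.2 | response lag (see below) |
| `leak` | fraction | 0.15 | intended activation bleeding to the opposing channel |
| `fatigue_rate` | /s | 0.001 | multiplicative growth of noise during tracking |
| `learning_factor` | — | 0.75 | per-session multiplier on noise, |bias|, leak |

Noise is Gaussian on the envelope (post-RMS) scale and clipped at zero;
envelope-level Gaussian noise is the simplest model that perturbs every
score in the battery. `lag_s` acts as a first-order time constant in
step-like tasks (MVC ramp, goal approach), but as a pure reaction
*delay* in sine tracking: a tracker who is consistently late
reproduces the waveform shifted in time, which a first-order filter
cannot represent — and a 2 s delay puts the composite in exact
antiphase, reproducing the qualitative failure mode of a
half-period-shifted tracker. Learning acts multiplicatively on
`noise_sd`, `|bias|` and `leak` only; the true MVC is held constant
across sessions, since the battery gives no mechanism for rapid true
strength change. Fatigue multiplies the tracking noise SD by
`(1 + fatigue_rate)` per second. The inter-mark pacing of the precision
task is not part of the protocol constants; the simulator uses a 2 s
idle gap and a 1 s approach before each 300 ms hold.

A cohort draws subjects' parameters uniformly from configurable ranges
(defaults: noise 0.02–0.06, bias ±0.05, lag 0.1–0.3 s, leak 0.05–0.30,
learning 0.60–0.85, 11 subjects, three sessions) and is fully
deterministic given one master seed.

What the generator does **not** emulate: motor-unit physiology,
electrode lift-off or sweat artifacts, within-session MVC drift,
correlated (non-white) envelope noise, and strategic behavior such as
re-anchoring to the on-screen bar. Passing round-trip tests therefore
demonstrates that the *scoring pipeline* is correct and sensitive to
the modeled effects; it does not validate the generator as a model of
human learning.

## The session comparison

Outcomes are aggregated to one value per subject × session × outcome ×
intensity band (per-subject means; the paired design requires exactly
one value per subject per cell). For each outcome, the Shapiro–Wilk
test at α = .05 on the paired first-versus-last-session differences
gates the comparison: normal differences go to paired *t* tests,
non-normal ones to related-samples Wilcoxon signed-rank tests (exact
null distribution for n ≤ 25 without ties, normal approximation with
continuity correction otherwise; all-zero differences are degenerate
and reported as p = 1). Session contrasts (three pairs) and
intensity-band contrasts (three pairs) form separate Bonferroni
families, each of size three, matching a design that compares "across
sessions" and "across levels" as two questions. Tests are two-sided —
improvements are expected but not assumed — and dispersion is always
the sample (n−1) standard deviation. The significance level is α = .05
throughout.

Calibration of the whole routing-plus-testing pipeline is checked by
simulation: on null outcome tables (no session effect, 1000
replicates) the per-comparison type-I error of the primary contrast
must lie in [0.03, 0.07], and the Bonferroni-corrected family-wise
rate must stay at or below α. The corrected family-wise rate is
conservative (the three pairwise session contrasts are correlated), so
it is asserted against the upper bound only. Power is checked on full
signal-level cohorts: with 11 subjects and a learning factor of 0.5,
the Pre-versus-Follow-Up precision improvement must be detected (after
correction) in at least 90 % of 50 simulated cohorts.

## Numerical choices and degenerate inputs

* Envelope traces must be non-negative and uniformly sampled; the CSV
  loader verifies time-column uniformity to a relative tolerance of
  1e-6 of the sampling interval.
* Windows are indexed in samples; a 30 s window at 100 Hz is exactly
  3000 samples, and partial trailing windows are not scored.
* A window whose reference has zero variance cannot be scored
  (undefined denominator) and returns `NA`; this cannot occur with the
  default sine and 30 s windows.
* `bin_intensity` uses a `floor` with a 1e-12 guard so that levels
  sitting exactly on a band boundary classify into the upper band on
  all platforms.
* Constant vectors fail the normality gate explicitly ("degenerate:
  zero variance") rather than erroring inside `shapiro.test`.
* All simulation entry points take explicit seeds, restore the
  caller's RNG state, and are byte-reproducible.

## Problem sizes

The shipped tests and the acceptance script use the protocol-sized
battery throughout: 30 marks per electrode, 300 s endurance sessions
(10 windows), cohorts of 11 subjects × 3 sessions. Monte-Carlo checks
use 1000 replicates for the type-I calibration of the report-level
pipeline, 50 full signal-level cohorts for power, and 5–30 seeds for
the smaller distributional properties; a full cohort through all four
assessments simulates in about one second.

## A worked example

```{r, eval = FALSE}
cfg <- assessment_config()
schedule <- generate_goal_schedule(cfg)

subject <- subject_model(seed = 42)
calib <- calibrate_mvc(simulate_mvc_trials(subject, cfg), cfg)

session <- simulate_goal_session(subject, schedule, cfg)
precision <- score_precision(session$recording, schedule, calib,
                             session$mark_windows, cfg)
separation <- score_separation(session$recording, schedule, calib,
                               session$mark_windows, cfg)
endurance <- score_endurance(simulate_tracking(subject, 300, cfg), calib, cfg)

report <- simulate_cohort(cohort_spec(master_seed = 7))
route_tests(report)
```

## Known limitations

* The volt scale is arbitrary and uncalibrated across hardware; only
  MVC-relative quantities are comparable between subjects or sessions.
* `best_r2` compares runs of different lengths by their mean window
  score; a long mediocre run can outrank a short excellent one only if
  its mean is higher, but the statistic is still length-sensitive near
  the 200 s boundary.
* The Wilcoxon exact path requires untied absolute differences;
  heavily tied percent-active outcomes fall back to the normal
  approximation.
* The simulator's learning model is multiplicative and monotone; it
  cannot produce the transient post-session performance dips real
  participants show.
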