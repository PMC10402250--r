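---
title: "Measuring reflexive pitch-shift responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring reflexive pitch-shift responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`pitchshiftr`: the measurement model, the synthetic-data generator that the
validation rests on, the statistical models, and the places where the
design was genuinely open and a convention had to be fixed.

## The measurement model

A pitch perturbation experiment yields, per trial, a voice f0 contour and
the onset time and direction of a brief feedback shift (+200, −200 or
0 cents; 200 ms). The quantity of interest is the reflexive pitch-shift
response: a transient deviation of produced f0, beginning roughly 60 ms
after the shift and peaking around 200 ms, whose direction usually opposes
the shift. The package's chain mirrors the standard analysis:

**Cent scale.** All response analysis is done in cents,
`1200·log2(f2/f1)`, so that speakers with different habitual f0 are
comparable. Within each epoch (−50 to +400 ms around the shift onset) the
reference `f1` is the *mean f0 in Hz* over the half-open baseline window
[−50, 0) ms. Because the log of a mean is not the mean of logs, the cents
of a baseline with nonzero variance average not exactly to zero but to
−(σ/μ)²/2 nats ≈ −0.1 cents at realistic jitter; this Jensen gap is
orders of magnitude below the measured effects and is accepted rather than
hidden by re-centering raw epochs. Sentence-task *difference waves* are
re-centered exactly (in cents) after template subtraction, because there
the zero line carries meaning for peak measurement.

**Window conventions.** Baseline [−50, 0) ms half-open; post window
(0, +400] ms; peak search (60, 300] ms, half-open at 60. The source
literature states spans but not endpoint inclusion; half-open intervals
make every frame belong to exactly one window. Ties at equal extrema take
the earliest frame, for reproducibility. Up to 20% of an epoch's frames
may be missing (after gap interpolation) before the trial is excluded;
missing frames are ignored in all pointwise means.

**Difference wave.** Sentence epochs ride on phrasal intonation; the
participant × focus pointwise mean of control (0-cent) epochs — the
intonation template, requiring at least 5 control epochs per cell — is
subtracted from each perturbed epoch. Subtraction is done in cents, not
Hz: the cent transform precedes all averaging in this pipeline, and in
cents the subtraction is exactly linear in the injected response (the
test suite verifies that a noise-free difference wave *is* the injected
pulse, frame for frame). Templates and trials are aligned at perturbation
onset; since every sentence shift occurs at a fixed 50 ms after voice
onset (control trials carry 0-cent sham events at the same point),
onset alignment and voice-onset alignment coincide. Vowel-task epochs
pass through baseline-centered only — there is no intonation to remove,
and applying the subtraction there would only add template noise.

**Response direction.** An epoch is an *up* response when its post-window
mean exceeds its pre-window mean; *following* when that sign matches the
perturbation sign, *opposing* otherwise. An exactly zero difference — a
probability-zero event under continuous noise, but constructible — is
labelled `none` and excluded from averaging cells; a deterministic rule is
needed for reproducible tests. Peak polarity for measurement (maximum for
upward, minimum for downward responses) follows the cell's *response*
direction, not the perturbation direction: direction sorting immediately
precedes averaging, so "upward response" can only sensibly refer to the
sorted response.

**Cell accounting.** With two perturbation directions and two response
directions, each participant contributes up to 4 averaged responses in the
vowel task and 8 in the sentence task (× 2 focus); for 51 participants
that is 204 + 408 = 612 potential cells. Cells with no epochs are
non-responses; any cell with ≥ 1 epoch is averaged (the smallest published
cells are single-trial).

## The synthetic-data generator

The generator is the package's validation instrument: it produces
sessions whose ground truth is known exactly, under the study conditions
of the emulated paradigm.

**Design.** Vowel task: 2 blocks × 45 trials, 3-s vocalizations, two
shifts per trial with onset-to-onset intervals uniform in 700–900 ms
(the interval endpoint convention — onset-to-onset — is fixed here, as the
source conventions do not specify it) and the first onset uniform in
400–700 ms. Sentence task: 5 blocks × 50 trials, one shift 50 ms after
voice onset. Magnitudes (±200/0) are balanced and shuffled, within
focus × magnitude cells for sentences, so every condition exceeds 30
trials per focus. All onsets are snapped to the 5-ms frame grid.

**Trial synthesis.** On the frame grid,

f0(t) = baseline · 2^[(intonation(t) + Σ pulses(t) + jitter(t)) / 1200]

* *Intonation* (sentences): linear declination (−20 cents/s, centered
  mid-phrase) plus a pitch-accent plateau on the stressed OBJECT word
  whose height, intensity level and vowel duration depend on focus
  (defaults 51.07 vs 38.65 cents, 65.79 vs 65.31 dB, 235.84 vs 248.15 ms
  for corrective vs new). The plateau's cosine ramps sit just *outside*
  the word so the within-word mean equals the plateau height exactly,
  making the injected prosody parameters recoverable by the stressed-word
  measures. Carrier phrase: "lay" (new) / "not" (corrective) + "your
  OBJECT by your LOCATION", with 40-ms voicing breaks at the /t/ of "not"
  and the /b/ of "by".
* *Response pulses*: each non-control shift spawns one raised-cosine
  (Hann) pulse — smooth, compactly supported, with an analytic peak —
  of full width 200 ms. Its sign opposes the shift with probability
  `p_opposing` (default 0.512, the opposing fraction implied by published
  response-direction counts), its magnitude is mean-parameterised
  lognormal (positive and right-skewed) around the group × task × focus
  cell mean (defaults: vowel 34.69/42.70 cents control/ataxia; sentence
  93.12/115.89 new and 129.89/146.98 corrective), and its peak latency is
  normal around the response-direction mean (229.37 ms opposing,
  195.18 ms following — identical across groups, as no group latency
  difference is reported), truncated to [90, 285] ms to respect the
  physiologic range.
* *Jitter*: AR(1) f0 wander in cents (default sd 20 cents, correlation
  time 50 ms) — stationary, smooth at the frame scale, and averaging away
  at the CLT rate.

**Latency scatter and peak attenuation.** Averaging pulses whose peaks
scatter by σ_L attenuates the averaged peak by
½(1 + exp(−(πσ_L/(w/2))²/2)) for a Hann pulse of width w. With w = 200 ms,
σ_L = 30 ms would already shrink measured magnitudes to ~0.82 of truth —
a real phenomenon of event-related averaging, but one that would conflate
two generator parameters. The default therefore puts only 10 ms of
latency scatter *within* subject (attenuation ≈ 2%) and 30 ms *between*
subjects (which shifts cell means without smearing any single average).

**Pathologies.** 25% of trials are pathological: 90% mis-timed shifts
(the shift physically arrives 300–600 ms late in sentences, or overruns
the vocalization in vowels — the event's recorded onset moves with it,
as a timing pulse would), 5% tracking dropouts (150 ms of unvoiced frames
inside an epoch window), 5% disfluencies (a flag, standing in for the
human screening pass). Exclusion rules detect the first two from the data
alone; only the disfluency flag is taken from ground truth. The expected
exclusion fraction is therefore the injected 25%.

**What the generator does not emulate.** Real voices: formant structure,
creak, breathiness, microprosody, loudness–f0 covariation; the perceptual
consequences of the ~12-ms device delay (stored as metadata only);
participant strategies (volitional responses after 300 ms). Passing
recovery tests therefore demonstrates that the measurement chain is
correct and calibrated *under the generative model*, not that the tracker
or the exclusion heuristics are robust to every pathology of real
recordings.

## The pitch tracker

`track_f0()` is a frame-based autocorrelation tracker: 40-ms Hann window,
5-ms hop, normalized autocorrelation divided by the window's own
autocorrelation (removing the window-induced downward bias of the peak),
candidate peaks restricted to *local maxima* in the lag range
[1/f0_max, 1/f0_min] above the voicing threshold (default 0.45), a small
octave cost (0.02 per octave) so the period peak beats its subharmonic
duplicates, and local cosine interpolation of the peak lag — exact for a
pure tone, where parabolic interpolation is biased. Estimates are clamped
to the search range (default 75–500 Hz), so octave errors outside the
range are impossible by construction; no dynamic-programming octave path
is used (clean synthetic stimuli do not need it; noted as an extension
point). A frame is voiced if the corrected peak reaches the threshold and
the frame RMS exceeds an energy floor (10⁻³).

On pure tones the tracker is accurate to a fraction of a cent; on
synthesized speech-like contours the round-trip error is dominated not by
the tracker but by the physics of windowed estimation: any 40-ms-window
estimator reports a window average, so wander faster than the window is
unrecoverable. The round-trip property (< 3 cents RMS) is therefore
verified on random contours whose wander correlation time (150 ms) is no
shorter than the analysis window; the default trial generator's 50-ms
jitter deliberately violates this, which is fine because the default
pipeline consumes generated contours directly — tracking from audio is an
optional entry path, not a stage of the recovery chain.

Gap interpolation (`interpolate_unvoiced()`) fills unvoiced stretches up
to 100 ms linearly in Hz, flagging filled frames; longer gaps stay
missing. Linear-in-Hz across a curved pulse flank is an approximation:
on corrective sentences the /t/ break (~160–195 ms post onset) can sit on
the response flank, and the interpolated frames then deviate from the
true contour while all other frames remain exact — the test suite checks
exactly this decomposition.

## Statistical models

Three linear mixed-effects models mirror the standard analysis, all with
a random participant intercept: absolute magnitude ~ group + task +
perturbation direction + response direction; magnitude ~ focus × group on
sentence measures; latency with the first structure. Fits use
REML via `lmerTest` with Satterthwaite denominator df; least-squares
(model-based) cell means and pairwise contrasts come from `emmeans` with
Tukey adjustment (the source analyses do not state an adjustment; Tukey
is the conventional default for LS-means families). Effect sizes use
`d = 2t/√df`, the convention of the effect-size helper commonly used with
such models. Response direction is additionally modelled by logistic
regression (opposing vs following) on group, task, perturbation direction
and focus, with focus coded `none` for vowel measures so the vowel rows
need not be dropped; terms with a single observed level are removed
automatically and quasi-separation is reported as a warning, never
silently. Degenerate inputs with zero residual variance (constructed toy
data) break the Satterthwaite machinery; such fits fall back to a
fixed-effects model with participant as a blocking factor, flagged as
singular — estimates remain exact, inference is not meaningful there and
is not used.

Prosody: one mixed model per outcome (stressed-word mean f0 in cents re
the participant's session-median f0, mean intensity in dB, stressed-vowel
duration in ms) with focus as fixed effect, fitted on control trials
only. The cents reference for prosody is a package convention (the
published figures do not state theirs); the session median is robust to
the response pulses and to the accent itself.

## Validation sizes and calibration

The test suite and acceptance script size their simulations to run on a
single CPU in minutes while keeping Monte-Carlo error well inside every
tolerance: parameter recovery uses a 10+10-participant cohort at reduced
trial counts (24 vowel + 72 sentence trials per participant), which
yields ~240 averaged cells spanning magnitudes from ~30 to ~160 cents —
ample leverage for the slope-recovery check; type-I calibration uses 200
null replicates of a measures-level simulation (8+8 participants), whose
two-sided Monte-Carlo band at α = 0.05 is ±0.031; contrast recovery uses
a 22+29 measures-level cohort with 40 trials per cell. The
measures-level generator (`simulate_measures()`) draws averaged-cell
outcomes from the same subject/cell hierarchy as the waveform generator;
it exists so that hundreds of replicate cohorts are affordable, while the
full waveform chain is validated once by the recovery analysis.

## Known limitations

* The generator's response model is additive and stationary within trial;
  real responses can overlap nonlinearly with ongoing intonation
  adjustments.
* Direction classification near zero signal is noise-dominated (as it is
  in real data, where following responses may partly reflect chance);
  recovery analyses therefore sort cells by ground-truth direction, and
  the classifier is tested separately (perfect at zero noise, degrading
  monotonically with noise).
* The tracker has no octave-path smoothing and no creak handling; it is
  adequate for clean, modal synthetic voices and for the package's
  entry-path role, not a general-purpose replacement for mature trackers.
* Measured peak magnitudes carry a small positive bias at low
  signal-to-noise (the extremum of signal-plus-noise), visible as an
  intercept in the recovery regression; it shrinks with trials per cell
  at the CLT rate.
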