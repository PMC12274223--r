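---
title: "Temporal speech analysis with atas: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal speech analysis with atas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atas)
```

## The problem

Adults who stutter (AWS) pause differently from adults who do not (AWNS):
more often, for longer, and with different temporal regularity. Because
listener-based counts of stuttered syllables are notoriously variable
across raters, an automatic, purely temporal characterization of oral
reading is attractive: cut a recording into *vocal events* (stretches of
produced speech) and *pause events* (silent stretches), and summarize their
frequency, duration, and variability. `atas` implements that pipeline end
to end: preprocessing, event detection, thirteen fluency metrics,
group-comparison statistics, and group classifiers, plus synthetic
generators so every stage can be validated without recordings.

## Event detection

The detector works entirely in the time domain on a preprocessed (denoised,
trimmed, peak-normalized) signal:

1. **Blind segmentation.** The signal is cut into non-overlapping 3-s
   segments (`segment_duration_s`). Each segment contributes its own
   adaptive amplitude threshold, so slow loudness drift across a recording
   does not bias the labeling. A trailing remainder shorter than one
   analysis window is absorbed into the previous segment.
2. **Short-time features.** A 50-ms window (`window_ms`) slides in 1-ms
   hops (`hop_ms`). Each window yields its RMS energy
   \(E_{rms} = \sqrt{\tfrac1N \sum_n x[n]^2}\) and its zero-crossing count
   (strict sign changes; transitions into or out of exact zero do not
   count, so digitally silent audio has ZCR exactly 0).
3. **Dual-threshold labeling.** Within a segment, frames with RMSE above
   the segment mean *and* non-zero ZCR are non-silent; frames with RMSE
   below the mean *and* zero ZCR are silent. Frames matching neither
   conjunction are resolved by ZCR alone, because zero ZCR is the signature
   of gated silence. (With that tie-break the label is fully determined by
   the ZCR; the RMSE conjunctions are retained as stated and verified
   against a brute-force rule table in the test suite.)
4. **Regions.** Maximal runs of identically labeled frames become regions.
   A window is labeled silent only when it lies wholly inside silence, so
   region boundaries are anchored on the silent runs: the boundary entering
   a silent run is placed at that run's first window *start*, the boundary
   leaving it at its last window *end*. On clean signals this recovers the
   true voiced/silent transitions to within one hop; a symmetric
   window-center convention would instead shorten every pause by roughly
   the window length, which distorts the short/long pause split. Frames are
   computed across segment boundaries (each frame is thresholded against
   the mean RMSE of the segment holding its window start) so that an event
   straddling a 3-s cut is never split in two.
5. **Temporal thresholds.** Silent regions of at least 50 ms
   (`pause_min_ms`) become pause events; non-silent regions longer than
   100 ms (`vocal_min_ms`) become vocal events. Sub-threshold regions are
   absorbed into the running event on their left (leading ones merge
   rightward), and same-kind neighbors are merged, so events tile the
   recording and strictly alternate.
6. **Short/long split.** Pauses of 50-150 ms (inclusive) are *short*,
   pauses above 150 ms are *long* (`short_long_boundary_ms`). The boundary
   is inclusive on the short side. Oral reading shows a bimodal pause
   distribution, and the long mode carries most of the group signal.

Degenerate recordings (all silence, or uninterrupted voicing) yield a
single event rather than an error; the metric layer then reports the
statistics of the absent event class as missing.

## Preprocessing and the zero-ZCR premise

The silence criterion requires gated silence to have *exactly* zero
crossings, which raw recordings never satisfy. `reduce_noise()` therefore
combines three stages:

- **Spectral gating.** A per-frequency noise magnitude profile is estimated
  from the lowest-energy tenth of the short-time spectra (or from an
  explicit noise-only recording). Each STFT bin is reduced by
  `strength` times (profile mean + `gate_sd` standard deviations), floored
  at zero — conventional magnitude spectral subtraction with the gate
  threshold doubling as an oversubtraction term.
- **Downward expander.** Samples whose local 5-ms RMS (measured on the
  *input* signal) stays at the ambient level are flushed to exact zero.
  The ambient level is the median of the lowest decile of the local-RMS
  envelope; the stage only engages when that level sits well below the
  loud end of the envelope (a continuous tone has no noise floor and must
  pass through unchanged).
- **Gate floor.** Any output sample below `floor = 1e-4` (about the 16-bit
  quantization step) is set to zero.

The testable contract: on fixtures with voiced bursts at amplitude at least
0.3 over white noise at amplitude at most 0.05, silent-interval RMS drops
below 10% of its input value while voiced-interval RMS retains at least
80%. Normalization is peak normalization (max |x| = 1): the detector's
thresholds are scale-invariant, so only a bounded range is needed, and peak
scaling preserves waveform shape exactly. No resampling is performed;
every time parameter is converted from milliseconds to samples per file.

## The thirteen metrics

For a recording with passage word count \(W\) (default 236, the standard
adult oral-reading passage) and trimmed duration \(T\) seconds:
speech rate \(= W/(T/60)\) words per minute; total pause time; pause
count; mean pause and vocal durations (ms); pause and vocal duration
variability (coefficients of variation, sample SD over mean); and the
count, mean duration, and CV separately for short and long pauses.

Two decisions here were genuinely open:

- **Speech-rate denominator.** The full trimmed duration (vocal plus pause
  time), not voiced time only. With the word count fixed by the passage,
  "words per minute" is a gross rate; only under this definition can a
  slower rate reflect increased pausing rather than slower articulation,
  which is the contrast the group comparison is designed to expose. The
  denominator is an explicit argument for users who want the other
  convention.
- **Empty subsets are missing, not zero.** A recording with no long pauses
  reports `mean_long_pause_ms = NA` (and a singleton subset reports
  `NA` CV, since the sample SD needs two values). Zeros here would drag
  group means toward zero and manufacture spurious group differences.

## Group statistics

The statistical layer mirrors a standard assumption-driven GLM workflow:
variance inflation factors (definitional \(1/(1-R^2)\)); Shapiro-Wilk
normality checks with log-transform recommendations for positive skewed
metrics; the studentized Breusch-Pagan test (the \(nR^2\) LM form) driving
a weighted-regression flag; and a Poisson-dispersion check
(Pearson \(\chi^2\)/df plus the Cameron-Trivedi auxiliary regression,
one-sided at .05) driving negative-binomial selection for counts.
`build_model_plan()` turns the flags into a family per metric: weighted
Gaussian for heteroscedastic but otherwise well-behaved metrics, weighted
gamma (log link) for positive heteroscedastic metrics whose normality a log
transform does not repair, Gaussian on the log scale where the transform
does repair it, negative binomial (NB2, dispersion \(\alpha\) with variance
\(\mu + \alpha\mu^2\)) for overdispersed counts, and plain Gaussian
otherwise.

Fits use group (reference AWNS), sex (reference female), and age as
predictors. The weighting scheme for "weighted" fits is not uniquely
determined by a Breusch-Pagan diagnosis; we use inverse fitted-variance
weights from one auxiliary log-linear regression of squared OLS residuals
on the predictors (no iteration). This is the textbook feasible-WLS remedy;
in simulation at n = 35 it costs the group coefficient a small attenuation
(of order 1 wpm on the speech-rate contrast), which is why the parameter
recovery test pins the unweighted estimator to the generating value and
only requires the weighted estimator's distribution to bracket it.
Multiple testing over the thirteen group contrasts is controlled by
Benjamini-Hochberg at FDR .1; `adjust_fdr()` is `p.adjust("BH")` plus the
step-up rejection set, verified against a brute-force implementation of the
definition. Correlations with percent syllables stuttered (%SS) are Pearson
(two-sided); because it is unstated whether the non-stuttering group enters
at %SS = 0, both variants are computed (`subset = "ss_defined"` /
`"all_zero_fill"`).

## Classifiers

The feature classifiers are a decision tree (`rpart`) on all 13 metrics and
a random forest on 7 significance-selected metrics (speech rate, total
pause time, pause count, mean pause duration, vocal duration variability,
mean short pause duration, long pause count — the exact selection is not
published and is configurable). Validation runs 10 repetitions of
stratified 80/20 resampling plus stratified 3-fold cross-validation, all
under one explicit seed. The protocol name "3-fold leave-one-out" is
internally contradictory; we read it as stratified 3-fold CV and expose
true leave-one-out via `cv_folds = n`.

The sequence classifier operates on non-overlapping windows of 20
consecutive events with nine features per event: the seven recording-level
metrics (constant within a recording), an event-type code (vocal = 1,
short pause = -0.5, long pause = -1: sign separates vocal from pause,
magnitude separates the pause subtypes), and the event duration.
Recordings are split train/test/validation (29/4/2 for a 35-recording
cohort) *before* windowing; feature normalization uses training-set
statistics only, and training windows are augmented by circular rotation of
the event order (shifts of 5, 10, and 15 events; a shift of 20 is the
identity and is excluded). The window learner is a random forest on the
flattened 20 x 9 window, with window votes aggregated to a recording
prediction by majority, ties broken toward AWS (the clinically conservative
direction). A no-leakage property is asserted in the tests: perturbing a
held-out recording changes neither the normalization statistics nor the
predictions for other held-out recordings.

## Synthetic data: what it does and does not emulate

`make_synthetic_utterance()` builds audio as alternating tone bursts and
silences with 5-ms raised-cosine ramps (preventing onset clicks that would
inflate the ZCR) and uniform ambient noise, and records exact ground-truth
boundaries. The tone's phase is anchored per burst so that zero crossings
reach both burst edges; without this, a crossing-free tail of up to half a
tone period blurs each detected boundary by about a millisecond, which
matters when asserting the inclusive 150-ms subtype boundary. The default
tone is 440 Hz; the validation fixtures use 440/500 Hz. The generator's
detectability guarantee — voiced amplitude strictly greater than four times
the ambient amplitude — is the regime in which exact event recovery is
claimed (and enforced at construction). With ambient noise, the expander
erodes each boundary by a few milliseconds, so noisy validation fixtures
keep a guard band around the 150-ms boundary; the exact-150-ms case itself
is biased inward and therefore stays short.

`make_synthetic_cohort()` draws the 13 metrics from truncated normals at
the study cohort's group means and SDs (e.g. speech rate
163.12 ± 23.43 wpm AWNS vs 127.60 ± 38.11 AWS), counts from negative
binomials (long/short pause count dispersions 0.18/0.13) with
`pause_count = long + short` enforced by construction, sex ratios 10/18
and 12/17 male, truncated-normal ages, and %SS for AWS rows from
`1 + 0.08 * long_pause_count + N(0, 1.5)` clipped to [0.1, 40] — a linear
model chosen to reproduce the strong positive association between long
pause count and stuttering frequency without asserting its exact size. The
default `"table"` mode samples metrics independently per participant
(marginals only, since only marginals are published); `"mechanistic"` mode
instead generates an event sequence per participant (log-normal vocal and
long-pause durations, truncated-normal short pauses, alternating order)
and computes the metrics from it, which induces realistic
within-participant metric correlations and supplies the event sequences
the sequence classifier needs. Neither mode synthesizes intelligible
speech, formants, filled pauses, or actual stuttered phonation: passing
recovery tests shows the temporal logic is correct, not that the detector
is robust to real-world confounds such as breath noise, microphone
handling, or reverberation.

## Problem sizes and numerical choices

The validation suite runs at desk scale: 100 random utterances (3-6 bursts,
16 kHz) for event recovery; 1,000 random event lists against the
direct-formula metric oracle; 500 replicate cohorts at n = 17/18 for
coefficient recovery and null-calibration (Kolmogorov-Smirnov on group
p-values); 2,000 replicates for the size of the Shapiro-Wilk and
Breusch-Pagan checks; 200 for overdispersion power; and 50 seeds for the
classifier chance/above-chance checks. Tolerances follow the measurement
grid: detected boundaries are asserted within half a window plus one hop
(26 ms); the windowed RMSE of a unit sine within 1% of \(1/\sqrt2\);
BH against brute force exactly.

Numerical details worth knowing: RMSE/ZCR use cumulative sums (no per-frame
loops); ties at the segment-mean RMSE fall to the ZCR rule; the ISTFT
normalizes by the summed squared synthesis window with a floor that zeroes
the few edge samples where window overlap is negligible; truncated-normal
sampling rejects and errors if the acceptance region has mass below 1e-6
(an infeasible generator specification should fail loudly, not silently
shift the moments).

## Limitations

The detector labels all non-silent intervals as vocal: filled pauses
("um"), breath noise near the microphone, and non-speech transients count
as vocal events, and disfluency types (blocks, repetitions, prolongations)
are not distinguished. The statistics layer fits fixed-effects GLMs only.
Published headline numbers from the study cohort (group coefficients,
%SS correlations, 71-86% classifier accuracies) depend on recordings that
are not distributable, so the package validates against synthetic cohorts
at the published moments instead; quantities computed on such cohorts
land on the published scale but are not reproductions.
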