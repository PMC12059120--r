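---
title: "Trial-based analysis of calcium-imaging mismatch responses"
author: "ppcmismatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based analysis of calcium-imaging mismatch responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcmismatch)
```

## The experiment this package analyses

In the auditory-tactile sequence paradigm an awake head-fixed mouse learns
that a 1 s "looming" sound predicts an immediately following whisker
stimulus. A single imaging session presents, in order: a *sound* session
(~25 looming + ~25 non-looming trials, randomly interleaved), a *whisker*
session (~50 whisker-only trials), a *pairing* session (~20 sound+whisker
trials) and an *interleaved* session (~120 *matched* sound+whisker trials
randomly interleaved with ~30 *mismatch* trials in which the whisker
stimulus is omitted or its intensity changed). Layer 2/3 activity is
recorded with a genetically encoded calcium indicator at 30 Hz. Each trial
starts with 2 s of baseline, then a brief trial-start cue; the predictive
sound begins 1 s after the cue and the whisker stimulus follows the sound
offset, optionally after a configurable delay. Trials last 8-9 s with 2-5 s
inter-trial intervals.

The scientific quantities of interest are: which neurons respond to which
stimulus window (including the *scheduled* stimulus window of omission
trials — the mismatch response), how reliably they respond per trial, and
whether activity rises *before* the predicted stimulus (an expectation
correlate).

## The analysis model

**Normalization.** Raw fluorescence is converted per trial to
$\Delta F/F = (F - F_0)/F_0$, where $F_0$ is the mean over the 1 s window
before that trial's start cue. Because $F_0$ is per-trial, slow drift is
largely removed and the measure is exactly invariant to rescaling a
neuron's raw trace (a property the suite tests to $10^{-12}$).

**Single-trial response.** For a stimulus window anchored at time $a$, the
response is the mean $\Delta F/F$ over $[a, a+1\,\mathrm{s})$ minus the mean
over $[a-1\,\mathrm{s}, a)$. At 30 Hz both windows are exactly 30 frames
(durations convert to frames as `round(len * rate)`).

**Shuffle-null classification.** A neuron's per-window responses are
compared against a null of 1000 identically shaped window statistics placed
at uniformly random anchors within the *same session's* trials, drawn with
replacement and independently per neuron. This conditions the test on each
neuron's own noise statistics. Significance uses the two-sided
Wilcoxon-Mann-Whitney rank-sum test at $\alpha = 0.05$; no multiple-testing
correction is applied, matching the protocol. Null anchors are *not*
excluded from true stimulus windows by default — the literal "random events
from the same session" reading — which inflates a responder's null and is
therefore conservative for that neuron's own window; `buildNull()` exposes
`excludeFrames` for sensitivity analyses. Windows with fewer than five
trials are flagged `insufficient` rather than tested.

**Odd/even cross-validation.** Analyses of selected cohorts must not reuse
the data that selected them. A neuron is *selected* for a window when its
odd-trial (1st, 3rd, ... in presentation order) responses are significant
against the null *and* their mean is positive; all downstream statistics
(population averages, mean responses) use even trials only. We deliberately
compute the selection significance from odd trials alone: conditioning
selection on an all-trial p-value reuses the even trials and pushes the
even-trial means of the selected cohort systematically above zero under the
null, defeating the purpose of the split. With fully odd-based selection
the even-trial means of neurons selected from a pure-noise cohort are
centered on zero — the acceptance suite verifies this on an 800-neuron null
cohort. This is the one place the package departs from the convention of
defining selection as "significant overall and positive on odd trials";
`ClassificationRecord` rows keep both p-values (`p_value`, `p_value_odd`)
so either rule can be applied.

**Category assignment.** Each (session, window) pair in which a neuron is
selected contributes a label: looming / non-looming (sound onset), their
offsets, whisker, pairing, matched, and mismatch (the scheduled onset of
deviant trials). Labels are not mutually exclusive; overlaps such as
matched-and-mismatch neurons are preserved and countable with
`overlapCounts()`. Labels come from the positively modulated (`selected`)
cohort by default because a two-sided test alone also flags *negative*
excursions — e.g. a sound-onset responder is "significant" in the
sound-offset window simply because its transient sits in that window's
baseline; `categorize(selectedOnly = FALSE)` restores the literal rule.

**Response probability.** Per trial, the single-trial trace is smoothed
with a 1st-order Savitzky-Golay filter (150 ms window; at 30 Hz that is 4.5
frames, rounded up to the odd count of 5) and the 30 frames after stimulus
onset are compared with the 30 frames before by rank-sum; the trial counts
as responsive when $p < 0.05$ *and* the post-window median exceeds the
pre-window median (the direction a two-sided p-value cannot encode). The
probability is the responsive fraction over *all* trials, odd and even.
Smoothing is applied only inside this per-trial test and display paths,
never before classification.

**Population statistics.** Population averages are means over per-neuron
even-trial mean traces, baseline-corrected by subtracting the mean of the
baseline window from the entire averaged trace (so the corrected trace
averages exactly zero over the baseline; SEM is across neurons). When a
predictive sound precedes the stimulus, the baseline window is the sound
presentation window — this makes the delayed-stimulus sessions a parameter
change, not a special case. Mean stimulus responses are computed from
per-neuron average traces raised so their minimum is zero when negative
("shift"); since the response is a baseline *difference*, the raise is a
no-op for included traces, and `mode = "exclude"` is available because the
convention could also be read as excluding negative-minimum traces. The
pre-stimulus (expectation) response is the mean over the 0.5 s before
(scheduled) stimulus onset of the baseline-corrected average trace; session
contrasts use the two-sided Wilcoxon signed-rank test on neurons present in
both sessions (absent neurons are dropped, with a log entry).

## The synthetic-data generator

`simConfig()` / `simulateExperiment()` generate the full study conditions:
the session composition above, 30 Hz sampling, uniform 8-9 s trials and
2-5 s intervals, and a forward model

$$F(t) = F_b\,(1 + d(t))\,(1 + \textstyle\sum_i r_i(t)) + \varepsilon(t),$$

with baseline $F_b$ (default 100 a.u.), slow sinusoidal drift $d$
(amplitude 2% of baseline, 300 s period, random phase per neuron), white
noise $\varepsilon$ (sd 5% of baseline, i.e. ~0.05 $\Delta F/F$), and
transients $r_i$: a difference-of-exponentials kernel
$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ normalized to unit peak, with
$\tau_r = 50$ ms and $\tau_d = 1$ s as generic red-GECI-like kinetics (the
indicator's true kinetics are not specified by the protocol; both are
configurable). Responses are multiplicative in baseline so that downstream
$\Delta F/F$ is baseline-invariant by construction.

Planted responders are partitioned into categories by configurable
fractions with largest-remainder rounding. Each responder draws one
lognormal peak amplitude (default meanlog $\log 0.3$, sdlog 0.5) and emits
its transient on each trial of its category with per-trial probability
`reliability` (default 0.35, emulating the ~32-37% response probabilities
typical of this preparation). Category anchors: whisker/pairing/matched
responders fire at stimulus onset of their session's trials; *mismatch*
responders fire at the *scheduled* onset on mismatch trials only (omission
responses, not stimulus responses); sound and sound-offset responders fire
at the looming-sound onset/offset. *Ramp* neurons are matched responders
that additionally carry a deterministic linear $\Delta F/F$ ramp from sound
onset to (scheduled) stimulus onset on every matched trial, peaking at
`prestimRampAmp` (default 0.2) — the expectation correlate. A configurable
number of mismatch neurons (default 7) also respond on matched trials,
planting a known matched-and-mismatch overlap. Mismatch amplitudes are
scaled by 1.5 by default so that the planted mismatch population response
exceeds the matched one, mirroring the observed ordering.

Default category fractions are whisker 0.24, pairing 0.12, matched 0.14,
ramp 0.08, mismatch 0.10, sound 0.10, sound-offset 0.10 (12%
non-responders). The recorded per-session responsive fractions this
emulates (≈39% whisker, 19% pairing, 33% matched, 8% mismatch) describe
*overlapping* populations and sum above one, so they cannot be planted as a
disjoint partition; the defaults keep their ordering (whisker > matched+ramp
> pairing > mismatch) while giving every class enough members for stable
per-class recovery statistics.

What the generator does **not** emulate: whisker motion and its neural
correlates (no motion channel is produced), cross-session suppression of
whisker/pairing responders outside their own sessions (planted responders
are silent outside their category's trials), neuropil contamination, spiking
biophysics beyond the kernel, and motion artifacts. Passing recovery tests
therefore demonstrate the *statistical machinery*, on data whose
trial-to-trial variability is simpler than a real recording's.

## Numerical choices

* Time-to-frame conversion: `round(t * rate)` everywhere, windows half-open
  `[start, end)`; 1 s at 30 Hz is exactly 30 frames.
* Savitzky-Golay edges: smoothed with the filter's polynomial edge rows
  (fits to the first/last full window), so constants and linear ramps are
  reproduced *exactly* over the whole series, including edges. Mirror
  padding was considered and rejected: a mirrored edge of a ramp is no
  longer linear, so an order-1 filter would distort edge frames.
* Degenerate baselines: $F_0 \le 10^{-6} \cdot \mathrm{median}(F)$ raises an
  error naming neuron and trial rather than producing silent infinities.
* Rank tests: exact enumeration when the smaller sample has at most 8
  observations (25 for the signed rank) and the data are tie-free;
  tie-corrected normal approximation with continuity correction otherwise.
  The suite checks the exact path against brute-force enumeration over all
  group assignments / sign patterns for every size up to $n + m = 10$.
  Fully tied inputs return $p = 1$.
* Null draws are with replacement, anchored anywhere within a trial snippet
  where both windows fit (they may span event boundaries within a trial,
  but never cross trials); whether the protocol sampled with or without
  replacement is unspecified, and with-replacement is the neutral choice at
  1000 draws.
* Seeds: one master seed is expanded into fixed per-stage substreams
  (schedule, truth, traces, null placement), so identical seeds give
  byte-identical schedules, recordings, classifications and reports, and
  any stage can be reproduced in isolation.

## Known limitations

**Power of the shuffle test at protocol trial counts.** With per-trial
reliability ~0.35, a responder's single-trial responses are a 65/35 mixture
of null-like and clearly super-null values. The rank-sum statistic against
the 1000-draw null is then bounded by the responsive fraction — responsive
trials cannot rank higher than the entire null — which caps detection
sensitivity at roughly 0.5-0.85 for sessions with 20-50 trials at
$\alpha = 0.05$, independent of the noise level. Per-category recovery
(Jaccard against planted truth) on the default cohort consequently reaches
~0.8 only for the 50-trial whisker session; `scripts/acceptance.R` computes
and reports the measured values. In the noise-free, high-reliability regime
the classification recovers every planted category and the planted
7-neuron matched-and-mismatch overlap exactly.

**Anti-conservatism of the per-trial response test.** Smoothing introduces
serial correlation between the frames entering the 30-vs-30 rank-sum, which
the test does not model; under finite noise the one-directional per-trial
false-positive rate is far above $\alpha/2$ (the acceptance script measures
it on a pure-noise cohort as `response_probability_null_rate`). Response
probabilities on noisy data are therefore upward-biased by roughly that
rate times the non-responsive trial fraction; recovery of planted
reliability to binomial accuracy holds in the noise-free regime, which is
what the reliability-grid check uses. The unsmoothed variant
(`smooth = FALSE`) is close to nominal size.

**Problem sizes.** Verification cohorts are chosen to make their own
statistics stable: 1000 neurons x 50 trials for test-size calibration, the
full 834-neuron default cohort for recovery, 20 neurons x 150 trials per
reliability point, 100 neurons (50 with ramps) per expectation condition,
800 neurons for the selection-bias check.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(sim = simConfig(nNeurons = 200L), seed = 1L)
report <- runPipeline(cfg, outDir = "out")
report$category_summary
report$recovery
```
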