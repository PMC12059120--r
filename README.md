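# ppcmismatch

Trial-based analysis of two-photon calcium-imaging recordings from
auditory-tactile stimulus-sequence experiments, for researchers studying
predictive processing in sensory cortex: which neurons respond to a
whisker stimulus, to the sound that predicts it, to the *omission or
deviation* of the predicted stimulus (mismatch responses), and whether
activity rises before the predicted stimulus (an expectation correlate).

## The statistics at the core

* **Per-trial normalization** — ΔF/F = (F − F₀)/F₀ with F₀ the mean over
  the 1 s window before each trial's start cue.
* **Shuffle-null responsiveness** — a neuron's single-trial responses
  (mean ΔF/F over 1 s from stimulus onset minus the 1 s baseline before
  it) are compared against 1000 identically shaped windows placed at
  random positions within the same session's trials, with a two-sided
  Wilcoxon–Mann–Whitney test at α = 0.05. This conditions significance on
  each neuron's own noise. Mismatch windows use the *scheduled* stimulus
  onset of deviant trials.
* **Odd/even cross-validation** — neurons are selected on odd trials
  (significant against the null and positively modulated) and every
  reported statistic uses even trials only, so selection bias cannot leak
  into the reported means.
* **Response probability** — per trial, the Savitzky–Golay-smoothed trace
  (1st order, 150 ms) is tested 30 frames after vs 30 frames before
  stimulus onset (rank-sum, p < 0.05, post median above pre median); the
  probability is the responsive fraction over all trials.
* **Population metrics** — baseline-corrected population averages (zero
  mean over the baseline window by construction), mean stimulus responses
  from even-trial average traces, pre-stimulus (0.5 s) expectation
  responses with paired signed-rank session contrasts, and category
  overlap counts.

A synthetic-data generator (`simConfig()`, `simulateExperiment()`)
reproduces the session structure of the paradigm — sound (25+25), whisker
(50), pairing (20), interleaved (120 matched + 30 mismatch) trials at
30 Hz — with GECI-like transients, per-trial reliability, lognormal
amplitude heterogeneity, drift, noise, planted category-specific
responders (including omission-mismatch responders and pre-stimulus
ramps) and full ground truth, so every stage of the pipeline is testable
against known truth.

## Worked example

```r
library(ppcmismatch)
cfg <- pipelineConfig(sim = simConfig(nNeurons = 200L), seed = 1L)
report <- runPipeline(cfg, quiet = TRUE)
report$category_summary
```

```
             window n_selected fraction
1           looming         20    0.100
2        nonlooming          8    0.040
3    looming_offset         19    0.095
4 nonlooming_offset          7    0.035
5           whisker         49    0.245
6           pairing         16    0.080
7           matched         40    0.200
8          mismatch         15    0.075
```

`n_selected` is the number of neurons passing the shuffle test and the
odd-trial positive-modulation filter for each stimulus window: here 49 of
200 neurons (24.5%) are whisker-responsive and 15 (7.5%) report the
omission of the predicted stimulus. On synthetic input the report also
contains recovery against the planted truth:

```r
report$recovery
```

```
      category          label n_true n_detected n_both   jaccard
1      matched        matched     51         40     37 0.6851852
2     mismatch       mismatch     20         15     13 0.5909091
3      pairing        pairing     24         16     12 0.4285714
4        sound        looming     20         20     15 0.6000000
5 sound_offset looming_offset     20         19     13 0.5000000
6      whisker        whisker     48         49     43 0.7962963
```

Recovery is limited by the power of the rank-sum test at the protocol's
trial counts when responders fire on only ~35% of trials — the methods
vignette quantifies this cap; in the noise-free high-reliability regime
recovery is exact. Mean response probabilities of the selected cohorts
(`report$response_probability`, here ≈ 0.44 per window) sit above the
planted per-trial reliability of 0.35 because the smoothed per-trial test
is anti-conservative under noise, which the vignette and the acceptance
outputs document. The mismatch-vs-matched population contrast is in
`report$matched_mismatch_comparison` (here medians 0.101 vs 0.077,
p = 0.060 at this cohort size).

Command-line wrappers for the three stages live in `inst/scripts/`
(`simulate.R`, `classify.R`, `run_pipeline.R`).

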