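---
title: "Cortical state segmentation and state-dependent firing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical state segmentation and state-dependent firing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortstate)
```

## The scientific problem

Cortical population activity moves between two regimes.  In the
*synchronized* state — typical of slow-wave sleep and most anesthesia —
activity alternates between phases of generalized spiking ("up" states)
and silence ("down" states), producing large low-frequency fluctuations
in the local field potential (LFP).  In the *desynchronized* state,
typical of active wakefulness, firing is tonic and low-frequency LFP
power collapses.  How a switch between these states reshapes the firing
of individual cells depends on cell class and cortical layer: in rat
auditory cortex, superficial pyramidal cells (PCs) and fast-spiking
interneurons (FSs) are suppressed during desynchronization, while deep
PCs show heterogeneous changes, with high-rate cells more likely to be
enhanced.

`cortstate` implements the full analysis chain needed to quantify this
pattern from laminar extracellular recordings — state segmentation from
LFP power, up/down detection from multiunit activity (MUA), waveform
based cell-type and layer classification, and state-modulation
statistics — together with a synthetic laminar-recording generator that
provides ground truth for every stage.  Because no public dataset
accompanies the original recordings, validation is by *parameter
recovery*: the generator is configured with the published values (state
epoch durations, class baseline rates, burst fractions) and the
pipeline must re-estimate them.

## The state-evaluation statistic

States are evaluated at 1-s resolution from the total spectral power of
the LFP at 0–7 Hz.  Each non-overlapping 1-s bin is demeaned,
Hann-tapered, and Fourier transformed; power is summed over frequencies
in (0, 7] Hz (DC is excluded after demeaning) and normalized so that the
total over all frequencies equals the taper-weighted signal variance
(Parseval).  The default channel is the first channel of the deepest
third of the probe, reflecting the infragranular bias of the original
measurement; `channel = "mean"` averages band power over all channels
instead.

The paper does not state how the power series was thresholded into
states, so the package uses a deterministic, parameter-free rule: 1-D
k-means (k = 2) on log10 band power, with centers initialized at the
data minimum and maximum; the lower-power cluster is desynchronized.
Labels are median-smoothed over 5 bins and runs shorter than
`min_epoch_s` (default 10 s, matching the generator's epoch truncation)
are merged into their neighbors — the analyzed epochs are of order 100 s,
and smoothing prevents label flicker.  If the two centers are separated
by less than 1% of the log-power range, the series is declared
degenerate ("no state alternation detected") and labeled against the
global median with a warning.

Up/down phases are recognized from MUA: pooled spike counts in 10-ms
bins, Gaussian-smoothed (sigma = 30 ms), thresholded within each
synchronized epoch at 20% of the mean up-phase rate.  The threshold is
iterated twice (first against the epoch mean, then against the mean of
the provisional up bins), which makes it insensitive to the up/down duty
cycle.  These constants are package choices — the source describes the
recognition only qualitatively — and are exposed as arguments.

For evoked desynchronization, firing rates are compared between the 2-s
windows immediately before stimulation onset and immediately after
stimulation offset.  A stimulation is counted *effective* when the
post-window 0–7 Hz power falls below half the pre-window power (the
factor is configurable); rate comparisons use effective events only by
default.

## Cell classification

Three features are measured on the mean waveform of the channel nearest
the soma: trough-to-peak time, half-amplitude width of the trough (with
linear interpolation between samples), and the asymmetry index
`(aR - aL)/(aR + aL)` of the baseline-to-peak amplitudes flanking the
trough.  Baseline is the mean of the first 20% of the waveform window;
peaks that do not rise above baseline are clipped to zero and flagged.
Units are split into putative FS (narrow spikes) and PC by k-means
(k = 2) on the z-scored features — the features have incommensurate
units, so z-scoring is required even though the source does not state
its scaling — with 50 restarts under a fixed seed for determinism.

Depth is the channel of maximum peak-to-trough amplitude (ties go to
the shallower channel, conservative toward the sparser superficial
class); layers are the published windows, inclusive: 0–500 µm
superficial (putative L2/3), 800–1100 µm deep (putative L5), everything
else unassigned.  Units enter the analysis only with isolation distance
≥ 20; the isolation distance of a sorted cluster is the squared
Mahalanobis distance (with respect to the cluster's own covariance) of
the n-th closest non-member, n the cluster size, infinite when fewer
non-members than members exist, and ridge-regularized
(`1e-6 x trace`) with a flag when the covariance is singular.

## State-modulation statistics

For each unit the modulation index is

MI = (FR_d − FR_s) / (FR_d + FR_s),

with FR_s and FR_d the synchronized and desynchronized firing rates; it
is undefined when both rates are zero, and such units are excluded from
population statistics.  Spontaneous-mode rates are means of per-1-s-bin
counts; per-cell significance uses Welch's unpaired t-test between the
two states' bin counts (bin counts are heteroscedastic across states).
Evoked-mode rates are means over stimulation events, tested with a
paired t-test.  Population medians are tested against zero with the
two-sided Wilcoxon signed-rank test, exact for 25 or fewer non-zero
values without ties, zeros dropped.  Burst analysis computes the
fraction of inter-spike intervals at or below a window (default 20 ms,
with 10/15/25 ms variants) inside each state's epochs; intervals
spanning an epoch boundary are discarded to avoid artificial long
intervals.  Class-by-state burst comparisons use a Kruskal–Wallis test
followed by per-class two-sided rank-sum tests, uncorrected by default
to match the per-class reporting convention (a `p_adjust` method is
available).  The dependence of modulation on baseline rate is the
Pearson correlation and least-squares line between log10(FR_s) and MI
(zero-rate units excluded, as a semi-logarithmic plot implies).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not the biophysics of the tissue:

* **State sequence.**  Alternating epochs with left-truncated
  exponential durations: no epoch shorter than 10 s, and the truncated
  distribution's mean equal to the configured per-state mean, so the
  published values (anesthetized 167/165 s, unanesthetized 197/423 s
  for synchronized/desynchronized) are directly recoverable.  An
  infinite mean yields a single-state recording.
* **Up/down phases.**  Exponential phase durations, default means
  0.5 s/0.5 s at 10-ms resolution.  The source shows but does not
  quantify the slow oscillation; these are conventional values for
  urethane anesthesia and are user-overridable.  A `down` mean of 0
  gives tonic (homogeneous Poisson) synchronized firing, used by the
  closed-form burst tests.
* **Spike trains.**  Inhomogeneous Poisson: rate `baseline/up_fraction`
  in up phases (so the synchronized-state average equals the class
  baseline, and published baseline rates are recoverable), zero in down
  phases, `baseline x gain` in desynchronized periods.  Each spike
  initiates a doublet with probability `burst_prob`, appending one
  extra spike at an exponential lag (mean `burst_isi_ms`, default
  5 ms); extra spikes multiply all rates by `(1 + burst_prob)`, and the
  condition presets therefore default to `burst_prob = 0` so that the
  preset rates equal the published ones exactly.  Per-unit baselines
  are log-normal around the class mean with the arithmetic mean
  preserved, and per-unit gains can depend on baseline rate
  (`gain_slope`), which is how the preset encodes the published
  positive rate–modulation relation among deep PCs.
* **Waveforms.**  A three-Gaussian biphasic template (negative trough
  with two positive flanks) solved in closed form to hit the three
  features exactly; re-measurement with the package's own extractor
  agrees within one sample period.  Class templates default to
  0.70/0.35/0.10 (PC) and 0.35/0.20/0.40 (FS) for trough-to-peak (ms),
  half width (ms) and asymmetry.  Amplitude decays across channels as a
  Gaussian in depth distance (sigma = 50 µm against 100 µm site
  spacing — only the relative ordering matters for depth estimation).
* **LFP.**  Broadband Gaussian noise everywhere plus, during
  synchronized periods, a slow component sign-locked to the up/down
  labels and a continuous within-phase oscillation (default 3 Hz, 30%
  of the slow amplitude).  The within-phase component ensures that even
  a 1-s bin spent entirely inside one phase carries low-frequency
  power; without it, roughly `exp(-2)` of synchronized bins would be
  indistinguishable from desynchronized ones at 1-s resolution.  With
  the default 10:1 amplitude ratio the per-bin log-power distributions
  of the two states are disjoint.
* **Determinism.**  One integer seed drives named substreams
  (`state-sequence`, `updown-phases`, `spikes:<unit>`, ...), so a
  dataset is bit-reproducible from its configuration and re-running one
  stage never perturbs another.

What the generator does *not* emulate: biophysical LFP structure,
overlapping-spike raw traces and sorting errors, electrode drift,
non-exponential epoch statistics, or anesthetic pharmacology.  Passing
tests therefore demonstrate that the estimators are correct and
calibrated under the assumed statistical structure, not that they are
robust to every failure mode of real recordings.

## Numerical and statistical choices

* **Epoch-mean recovery.**  The last epoch of a recording is
  right-censored; averaging only the epochs that fit inside the window
  under-represents long epochs and biases the mean low by ~10–20% at
  the validation scale.  `epoch_duration_means()` therefore uses the
  renewal maximum-likelihood estimator — total state time divided by
  the number of completed epochs — treating the epoch that begins at
  time 0 as complete (exact for the simulator, whose recordings start
  at an epoch onset).
* **Burst calibration.**  The closed form for the expected burst
  fraction combines the doublet-lag term with the probability that the
  next seed spike arrives within the window before the up phase ends
  (`lambda/(lambda+eta) (1 - e^{-(lambda+eta)w})`, `eta` the up-phase
  exit hazard); re-entries into a later up phase within the window are
  neglected, which the validation study bounds at about 0.001 in
  fraction.  At the unanesthetized deep-PC rate (4.5 Hz baseline, up
  fraction 0.5) the Poisson floor of the synchronized-state ≤20 ms
  fraction is ≈ 0.162, slightly above the published 0.16, so
  `solve_burst_prob()` clamps at zero with a warning and the attainable
  fraction (within 1% of the published value) is the calibration
  target.
* **Test calibration.**  Under the up/down generator, adjacent 1-s bin
  counts are negatively serially correlated, which makes the
  spontaneous-mode unpaired t-test conservative (empirical size ~2–3%
  at alpha = 0.05 over 1000 simulated null units; the design bound used
  in validation is 7.5%).  The evoked-mode paired t-test, whose events
  are independent, is calibrated within the binomial confidence
  interval of alpha.
* **Validation problem sizes.**  Rate recovery uses 30 units over
  3000 s per class; epoch recovery 30 recordings of 1800 s
  (anesthetized) or 3600 s (unanesthetized); burst recovery 30 units
  over 2000 s; calibration 1000 null and 100 alternative seeds.  With
  ~150–180 completed epochs, the epoch-mean estimator carries a ~7.5%
  coefficient of variation — recovered values scatter accordingly, and
  that scatter is a property of the problem size, not of the
  estimators, which the tests verify to be unbiased against ground
  truth.

## Known limitations

* The two-state model is binary; intermediate or drifting states are
  forced into one class, and the degenerate (unimodal power) case is
  detected only when cluster separation collapses below 1% of the
  log-power range.
* Up/down detection pools all units; it requires a pooled synchronized
  rate of at least 0.5 Hz and is undefined (flagged) below it.
* The FS/PC split is a two-cluster model; narrow-spiking pyramidal
  cells, reported in primates, would be misassigned.  Depth estimation
  assumes the largest waveform marks the soma, which somato-dendritic
  backpropagation can violate in large PCs — the conservative,
  deliberately non-contiguous layer windows (0–500, 800–1100 µm) exist
  precisely to absorb that risk.
* Evoked and spontaneous modes share the modulation-index machinery but
  differ in sampling units (events versus bins); their p-values are not
  directly comparable.
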