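---
title: "Decoding the identity of sensory prediction errors from population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the identity of sensory prediction errors from population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errdecode)
```

## The scientific question

Midbrain dopamine neurons broadcast reward prediction errors: firing dips
when an expected reward is omitted and bursts when an unexpected reward
arrives. Averaged across neurons, this signal looks like a scalar — it says
*that* a prediction was violated and in which direction, but not *what*
exactly was mis-predicted. The analyses implemented here ask whether the
missing detail is nonetheless present in the *pattern* of firing across a
population: when a reward's flavor changes at unchanged value, can the
identity of the new flavor be read out from the joint activity of many
dopamine neurons, even though no single neuron distinguishes the flavors?

The package provides the full analysis chain for this question, together
with a synthetic-data generator that emulates the behavioral task and the
error-coding structure the analyses assume, so every stage can be validated
against planted ground truth.

## The task model

A session consists of five trial blocks at two reward wells. Rewarded
trials deliver drops of one of two flavored solutions (grape or tropical
punch), with multiple drops spaced exactly 1000 ms apart and a 500 ms odor
cue instructing the correct well:

1. three drops per trial (one flavor per side);
2. one drop (number downshift: the second and third drops are omitted);
3. three drops again (number upshift: the second drop is newly delivered);
4. all three drops switch to the other flavor on both sides;
5. only the second drop switches back, the flanking drops keeping block-4
   flavors.

Blocks 2 and 3 induce *value* prediction errors (less or more reward than
expected); blocks 4 and 5 induce *identity* errors (different flavor at
matched value). Because each side carries one flavor in blocks 1–3 and the
assignments flip in blocks 4–5, flavor is fully crossed with side in the
decoding datasets, so a flavor decoder cannot exploit spatial information.
Behavioral lapses (wrong well, no reward) occur at a configurable rate,
5% by default.

## The spike-train generator

Spikes are drawn from an inhomogeneous Poisson process by exact thinning
(`sample_poisson_spikes()`), so spike counts in any window are exactly
Poisson. Each unit's rate is a tonic baseline (uniform on 2–8 spikes/s by
default, the tonic dopaminergic range) plus event-locked bumps at light
onset, odor onset, well entry and each reward drop. Bumps are truncated
Gaussians peaking 200 ms after the event with 100 ms SD and 600 ms
support, so the standard 200–700 ms post-event analysis epoch captures
most of their mass.

Error signals multiply the drop response and decay exponentially over
trials within a block (per direction), with e-folding `flavor_decay_tau`
(default 5 trials):

* **Value errors.** A single latent sensitivity per unit scales a burst at
  the first newly delivered drop of block 3 and, with opposite sign, a
  multiplicative suppression (floored at zero, since rates cannot be
  negative) at the scheduled times of the omitted drops in block 2.
  Using one latent with opposite signs reproduces the inverse cross-neuron
  correlation between omission and delivery responses with a single
  parameter.
* **Identity errors.** At flavor-changed drops the drop response is scaled
  by `1 + (c_u + g_uf) * decay`, rectified at zero. The shared burst
  `c_u >= 0` (mean `flavor_common_gain`, default 0.5) models the
  flavor-unspecific surprise response — elevated firing at either flavor
  switch, positively correlated between the two flavors across neurons.
  The pattern component `g_uf ~ N(0, flavor_gain_sd)` is the signal of
  interest: a unit- and flavor-specific gain that makes the two flavors'
  errors separable across the population while leaving single-unit
  averages uninformative.

The magnitude and sparsity of real single-unit flavor gains are not known;
`flavor_gain_sd` is a free parameter of the simulation, not an estimate of
the recorded data. The default 0.6 produces moderate ensemble
decodability. The parameter-recovery tests and the bundled
reproduction script use the "strong" setting `flavor_gain_sd = 3` with
`flavor_decay_tau = 3`: with that decay constant the gain factor averaged
over a ten-trial window is only ~0.29 of its trial-1 value, so a gain SD
of 3 is what makes drop responses differ by multiples of their mean on
the earliest trials while the decay stays visible within ten-trial
windows.

Waveform features (spike-duration half-time, first-positive/first-negative
amplitude ratio) are drawn from a two-component Gaussian mixture; the
default wide and narrow components sit more than six pooled SDs apart,
matching the clear bimodality the waveform classification assumes.

## Unit classification

Units are clustered on z-scored waveform features by 2-means (100 seeded
restarts; the field's descriptions name no specific algorithm, so the most
conventional one is used). The cluster with the larger mean half-time is
"wide". Each unit is then re-assigned leave-one-out: cluster centers and
per-feature SDs (n−1 denominator) are recomputed without the unit, and the
unit joins a cluster only if its normalized Euclidean distance
`sqrt(sum(((x - mu)/sd)^2))` is at most 3 for exactly one cluster — within
3 of both, or of neither, leaves it unclassified. A per-feature `|z| <= 3`
variant is available (`metric = "per_feature"`); the Euclidean default
treats both features symmetrically. Reward responsiveness is a paired
t-test of the 500 ms pre-light-on baseline against the first 500 ms after
the first drop across rewarded trials (p < 0.05, two-sided). Putatively
dopaminergic = wide AND reward-responsive.

## Alignment, binning and difference scores

For time-resolved analyses, each trial's spikes are warped
piecewise-linearly so that five anchor events (light on, odor delivery,
odor-port withdrawal, reward delivery, light off) land on the
session-average anchor times; spikes outside the anchor span shift rigidly
with the nearest anchor. The warp preserves per-trial spike counts.
Warped trains are binned into sliding 900 ms windows; the step defaults to
100 ms, which resolves the 1000 ms inter-drop spacing (only the width is
conventionally fixed).

Transition difference scores compare the mean baseline-subtracted firing
rate (200–700 ms after the relevant drop) on the first three rewarded
trials after a transition against a five-trial comparison span: the last
five rewarded trials of the same block for number transitions, or of the
previous block for flavor transitions, always within direction, then
averaged over the two directions with equal weight (pooling trials across
directions instead is a one-line change; equal weighting was chosen so
each learned association contributes equally). Omission epochs anchor to
the *scheduled* second-drop time (first drop + 1000 ms). Rewarded means
correct-and-fluid-delivered, so one-drop trials count.

## Pseudoensemble decoding

The flavor dataset takes the first ten correct trials per flavor per
flavor-switch block — 40 trials per unit, flavor crossed with side — with
block-5 trials labeled by the second (changed) drop. Decoding uses a
correlation-template classifier: trials are divided into splits with one
test trial per class per unit per split, each unit's assignment drawn
independently (this random pairing across units is what makes the
population a *pseudo*ensemble); a test pseudo-trial joins the class whose
training-mean template it correlates with best across units. The split
assignment is redrawn on every resample (500 in the full profile), and
accuracy is the mean 1–0 loss over all test trials, splits and resamples.
With 20 trials per class and the default 20 splits, every trial is tested
exactly once per resample.

Numerical conventions: zero-variance vectors are assigned correlation 0 so
the argmax stays defined on silent-trial edge cases; exact correlation
ties are broken uniformly at random from the resample RNG (they have
probability zero for continuous rates).

One degenerate input deserves note: if the two classes contain *identical
copies* of the same trials, accuracy collapses far below chance rather
than sitting at 0.5, because each test trial's duplicate remains inside
the other class's training mean and inflates the cross-class correlation.
Exchangeability holds in the ordinary sense — classes drawn independently
from one distribution decode at chance, which is what the calibration
tests assert — but not under literal duplication. The engine was verified
decision-for-decision against an independently coded brute-force
correlation argmax.

Built on this core:

* **Sliding trial sets** re-run the analysis on windows of ten consecutive
  trials per flavor per block to expose the decay of the identity signal
  as the block progresses, alongside the per-window mean baseline rate.
* **Four-class early/late confusion analysis** pools both flavor-switch
  blocks, labels the first ten and last ten trials of each flavor
  separately, and decodes the four classes in the single 900 ms epoch
  starting 100 ms after the changed drop; the identical procedure at the
  flavor-unchanged control drops (first drop of blocks 3 and 5 — also
  parts of three-drop sequences with flavor crossed with side) gives the
  control matrix.
* **Latency scan**: a 200 ms epoch advances from the changed drop in
  25 ms steps (the step is configurable; sub-100 ms granularity is needed
  to resolve latencies between epoch boundaries) until the label-shuffle
  permutation p-value drops below 0.05 and stays there for at least five
  consecutive epochs; the latency is the end of the first such epoch, and
  a scan with no qualifying run reports "not reached".

## Permutation statistics

Chance bounds come from shuffling the flavor labels within block
(preserving the ten-per-flavor structure) and re-running the *entire*
analysis per shuffle — 100 shuffles in the full profile — taking the
per-point one-tailed 95% bound as the linear-interpolated empirical
percentile. A decoding curve counts as significant only where it exceeds
the bound for at least five consecutive trial sets, which controls the
family-wise rate across the many correlated windows. All permutation
p-values use the add-one estimator `(count + 1)/(n + 1)`, which cannot
return zero from finitely many permutations.

The confusion-matrix pattern test asks whether decoding is specifically
early and transition-locked: the statistic pair is `D_early` and
`D_late`, the summed diagonal differences (transition minus control) over
the early and late classes. No closed formula for "the pattern differs"
is conventional here, so the diagonal differences are this package's
concretization. The null pairs randomly sampled label-shuffled matrices
from the two analyses (100,000 pairings in the full profile). Two
summaries of the verbal criterion — early difference as large as
observed, late difference as small — were considered. The literal
*conjunction* probability (null pairs extreme in both coordinates at
once) turns out not to be a calibrated p-value: a bivariate quadrant
probability behaves, for independent coordinates, like the product of two
uniforms, so nominal 0.05 rejects about 20% of null datasets. The
reported `p_value` therefore uses the scalar contrast
`D_early − D_late`, which is large exactly in the hypothesized direction
and whose permutation p-value is uniform under the null (the suite checks
this size control on simulated null sessions); the conjunction
probability is retained as `conjunction_p` for comparison. The
group-level variant builds 100 population-average null matrices by
sampling one shuffled matrix per subject and averaging, then pairs those
averages.

## Multivoxel pattern analysis

The MVPA stage starts from extracted response estimates (subject × run ×
condition × voxel); no image processing is performed. Thirteen conditions
per transition family mirror a reversal-learning design: the two error
trials (labeled by received flavor), each flavor at one to four trials
post-reversal, each flavor on the pre-reversal trial, and all others.

Voxels are sorted per subject by the difference between mean error-trial
and mean pre-reversal responses (combined across flavors and runs; stable
ties by index). Pairwise sweet-vs-savory decoding at a given trial point
uses a linear max-margin classifier (libsvm via e1071, cost 1 — the
conventional default where no value is specified) in a nested
cross-validation: for each held-out subject, the voxel count is chosen by
leave-one-subject-out decoding among the training subjects over a grid of
top-k counts (10, 20, … up to the ROI size; ties resolve to the smallest
count for parsimony and determinism), and the held-out subject is then
scored by leave-one-run-out decoding in that many of its own top-sorted
voxels. The held-out subject's data never touch its own voxel-count
selection — the suite asserts this by replacing a subject's data with
noise and checking its selection is unchanged. The inner selection
decodes at the same trial point being evaluated; selecting on the error
trial only is the natural alternative and would be a two-line change.

The pattern generator plants, on error-trial conditions only, a shared
activation with a fixed descending profile across the signal voxels plus
(in the flavor family) a flavor-specific pattern added for sweet and
subtracted for savory. The shared activation is what error-vs-pre sorting
can rank on — without a univariate error response the sorting step would
be uninformative, and its fixed profile is also what aligns sorted voxels
across synthetic subjects well enough for cross-subject decoding; real
subjects share no voxel space, and the generator does not emulate
between-subject misalignment beyond noise. The value family carries the
activation but no flavor pattern, so value-transition decoding of flavor
is at chance by construction.

## What passing tests do and do not show

The generator provides Poisson spiking, event-locked responses,
exponentially decaying planted error signals, bimodal waveform features
and sparse error-specific voxel patterns — the statistical structure the
analyses assume. It does not emulate drift or non-stationarity in
baseline rates, correlated noise across simultaneously recorded neurons
(irrelevant to pseudoensembles, which randomize pairing), bursting or
refractory spike-train structure, hemodynamic smoothing, or
between-subject voxel misalignment. Passing parameter-recovery tests
therefore show the chain is correct and calibrated on data satisfying its
assumptions, not that the assumptions hold for any particular recording.

## Problem sizes and reproducibility

The full replication profile (500 split resamples, 100 shuffles, 100,000
confusion comparisons) matches the published analysis scheme; the bundled
test profile (50 / 20 / 1,000) keeps exploratory runs fast. The
parameter-recovery and calibration checks in the test suite run 20
simulation seeds per property (50 for the
null size of the pattern test) with 20–30 resamples — at these settings
the Monte-Carlo error is small relative to the planted effects, and
calibration properties are invariant to the resample count because
observed and shuffled runs use identical settings. MVPA validation uses
7–10 subjects with 40–60 voxels; the session simulator always runs the
full five-block task with 25 trials per direction per block. Every public
generator and analysis takes a seed, derives per-stage streams from it
(`derive_seed()`), and restores the caller's RNG state, so identical
configurations and seeds give byte-identical outputs.

## A worked run

```{r, eval = FALSE}
cfg <- generator_config(flavor_gain_sd = 1.5, flavor_decay_tau = 3)
report <- run_ensemble_pipeline(cfg, seed = 1, profile = "test")

# decay of identity decoding across the block, with its chance bound
cbind(accuracy = report$decoding$transition$curve$accuracy,
      bound = report$decoding$transition$null$upper_bound)

report$confusion$transition      # early/late confusion, changed drops
report$pattern_test              # transition vs control pattern test
report$latency$latency_ms        # identity-signal latency, ms

mv <- run_mvpa_pipeline(seed = 1, profile = "test",
                        n_subjects = 10, n_voxels = 60,
                        n_signal_voxels = 10)
mv$accuracy$flavor               # sweet-vs-savory accuracy by trial point
```

## Known limitations

* The generator's flavor-gain magnitudes are free parameters; none of the
  recorded-data effect sizes are re-estimated here.
* The correlation-template classifier is the only decoder for the
  electrophysiology stage, matching the analysis being reproduced; no
  decoder comparison is attempted.
* Session I/O uses a documented CSV + JSON layout (`write_session()`);
  the trial table mirrors the columnar layout used by the archived
  recordings.
* The confusion-pattern statistic is one defensible concretization of a
  verbal criterion; the statistic function is injectable for sensitivity
  analysis.
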