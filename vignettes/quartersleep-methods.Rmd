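---
title: "Time-resolved PSG features and classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved PSG features and classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartersleep)
```

## The problem

Narcolepsy type 1 (NT1) shares daytime symptoms with narcolepsy type 2
(NT2) and idiopathic hypersomnia (IH), but its nocturnal sleep differs:
REM sleep tends to appear very early, sleep is fragmented (frequent
stage shifts, more N1 and wake), and "mixed" sleep/wake states are more
common. These differences are not constant over the night, so features
that resolve the sleep period into quarter-nights carry diagnostic
information that whole-night averages blur away.

`quartersleep` implements a complete, testable pipeline around that
idea: five interpretable feature sets extracted from standard overnight
recordings, a class-balanced resampled classification framework to
measure how well those features separate NT1 from other groups, a
per-feature statistical screen, and a synthetic cohort generator that
emulates the group-dependent sleep structure so every stage of the
pipeline can be validated without clinical data.

## Analysis window and quarter-nights

All features are computed on the *analysis window* running from
**persistent sleep onset** -- the first run of at least 5 minutes (10
consecutive 30-s epochs) of non-wake sleep -- to the final sleep epoch
of the recording. We read "continuous sleep" strictly: any wake epoch
breaks the run. The window is cut into four contiguous quarter-nights of
equal epoch count; when the length is not divisible by four, the
remainder epochs are assigned one each to the earliest quarters
(deterministic, and never more than one epoch of imbalance).

## Feature sets

| Set | Count | Contents |
|---|---|---|
| whole-night sleep metrics | 8 | stage proportions (W, N1, N2, N3, R), TST, SSI, REM-onset latency |
| quarter-night sleep metrics | 28 | stage proportions, TST, SSI per quarter |
| transition matrices | 100 | 5x5 row-conditional transition probabilities per quarter |
| qEEG | 120 | 6 relative band powers x 5 stages per quarter |
| hypnodensity | 64 | 5 marginals, 10 pairwise mixtures, entropy per quarter |

Design choices where the definitions left room:

* **Proportions** (including wake) are fractions of epochs in the
  window or quarter -- not of total sleep time -- so the five values sum
  to exactly 1.
* **TST** is reported in minutes; **SSI** (stage shift index) counts
  changes between adjacent epoch labels, wake included, per hour of the
  range.
* **REM-onset latency** is measured in minutes from persistent sleep
  onset (the start of the analysis window; lights-off is not available
  in hypnogram-only input). The reference point is a configuration
  choice in principle, and the accessor makes the window explicit.
  Nights with no REM at all get the full window duration as a sentinel
  (monotone: later-than-everything) plus a `rem_missing` metadata flag
  that is deliberately *not* one of the 8 features.
* **Transition matrices** are row-conditional probabilities rather than
  raw counts, making quarters of unequal length comparable; a
  counts-per-hour mode is available. Self-transitions are kept (the
  diagonal is where stage stability lives, and 25 entries per quarter
  requires it). Pairs straddling a quarter boundary are not counted, so
  quarters are independent. Rows for stages never visited as a "from"
  state are zeros, not missing values, so downstream models need no
  imputation for them (a visited-row mask is attached for diagnostics).

## qEEG

Band powers use the six-band scheme delta 0.5-4, theta 4-8, alpha 8-12,
sigma 12-16, beta 16-30, gamma 30-47 Hz. Each 30-s epoch is cut into
fifteen non-overlapping 2-s slices; a slice is rejected if it contains
clipping (any sample at or beyond the recorder limits) or a flat-line
(three or more identical consecutive samples). Per-slice spectra are
multitaper estimates with Slepian tapers computed from the standard
tridiagonal eigenproblem; the defaults are time-bandwidth product 2 with
3 tapers, a conventional variance/resolution compromise at 2-s windows,
and both are configurable. Band power is the rectangular integral of the
PSD over half-open `[low, high)` bins; relative power divides by the
total over all six bands, so valid slices sum to 1 by construction.
Epoch values average the valid slices; stage-conditional quarter
features average the valid epochs of that stage in that quarter.

Numerical caveats worth knowing:

* With 2-s slices the spectral resolution is 0.5 Hz and the multitaper
  smoothing bandwidth is about +/-1 Hz, so sharp spectral edges leak
  across band boundaries. On synthetic signals with piecewise-flat
  spectra this biases the narrow delta band by up to ~0.1 of relative
  power (the tests account for this); on broadband noise the band
  fractions are recovered to well under 2%.
* When the recording header provides no clip limits, the observed
  extrema are used (with a warning), so saturated-at-range segments are
  still caught.
* Epochs marked `no_score` in the hypnogram are excluded from qEEG
  aggregation; stage-by-quarter cells with no valid epoch are `NA` and
  are median-imputed *inside the training split* of the classifier,
  never from held-out data.

## Hypnodensity features

A hypnodensity gives each epoch a probability distribution over the five
stages instead of one label. Per quarter we average: each stage's
marginal probability; each of the ten pairwise products
`p_X * p_Y` (computed per epoch, then averaged -- the products are
where within-epoch state mixing shows up, which is the point of the
feature; the alternative product-of-quarter-means is available as an
option); and the per-epoch Shannon entropy, in nats (natural log;
configurable). 15-s hypnodensities are averaged in consecutive pairs
down to the 30-s grid first. Marginal means commute with that averaging
exactly (linearity); mixtures and entropy do not, which is documented
rather than hidden -- the tests check the marginals' exact commutation.

## Synthetic cohort generator

The generator exists so that the full pipeline -- extraction,
statistics, classification, importance -- can be exercised end to end
with known ground truth. Each group (NT1, NT2, IH, control) has a
profile: initial stage distribution, four quarter-specific 5x5
transition matrices, a gamma REM-latency distribution, a stage-by-band
EEG spectral weight table, a hypnodensity concentration, and an age
distribution matching the four groups' published means and SDs.

A night is a time-inhomogeneous Markov chain over the five stages (the
simplest mechanism whose quarter transition matrices the extractor can
recover *exactly*, closing the verification loop). REM latency is
imposed by suppress-then-release gating: REM is removed from the
transition rows until the subject's sampled latency has elapsed, after
which the first REM entry from sleep is floored at 0.12/epoch
("accumulated REM pressure") until REM first occurs -- without the
floor, realized latency would be the window plus a long, heavy-tailed
wait governed by the chain's baseline REM accessibility, and the
latency parameter would not actually control latency. With it,
realized latencies track the clinically cited values (NT1 roughly
32 +/- 19 min for the 30-min scale; controls roughly 89 +/- 55 min
for the 90-min scale, with a normal ~20% REM fraction). The gate is
part of the latency mechanism and is disabled when a zero latency is
requested, so the pure Markov chain is recoverable. Default night
length is 960 epochs (8 h). EEG is spectrally shaped Gaussian noise per
epoch (128 samples/s, enough to resolve 47 Hz), with optional injected
flat-line artifacts; hypnodensities are Dirichlet draws centred on the
true stage.

The default contrasts: NT1 has a 30-min REM-latency scale (its
clinically typical mean), moderately elevated off-diagonal transition
mass, transition mass into N1 that grows across quarters, slightly
drowsier wake/N1 spectra and more diffuse hypnodensities; controls and
IH have 90-min scales and stable, sticky architecture with normal REM
cycling; NT2 sits in between. The contrast magnitudes were calibrated
so that the feature sets' classification performance on synthetic
NT1-vs-control cohorts lands in the band reported for real cohorts
(each single set AUC roughly 0.75-0.93, all features best) rather than
separating the groups perfectly -- the point of the emulation is that
the pipeline must *discover* structure against realistic within-group
spread, not read it off. Cohort sizes default to 23/18/21/8
(NT1/NT2/IH/control), preserving the 114:41 NT1:control imbalance of a
clinical referral population at one-fifth scale.

Two levels of randomness are deliberately separated:

* `generate_hypnogram(profile, ...)` uses the profile matrices exactly
  -- this is the object whose transition structure is recovered in the
  round-trip tests.
* `generate_subject()` first *individualises* the profile: Dirichlet
  jitter of transition and band-weight rows (concentration
  `subject_kappa = 30`), a log-normal instability multiplier on the
  off-diagonal mass (`inst_sdlog = 0.5`), and log-normal jitter of the
  hypnodensity concentration (`conc_sdlog = 0.4`). Without this,
  every subject of a group is statistically identical and several
  features separate the groups perfectly, which no clinical cohort
  does; with it, within-group spreads (e.g. SSI roughly 24 +/- 14 per
  hour in NT1 vs 13 +/- 8 in controls) overlap realistically while REM
  latency remains the cleanest single discriminator -- the structure
  the classifier is supposed to discover.

What the generator does **not** emulate: ultradian REM/non-REM cycling,
bout-duration distributions, real EEG morphology (spindles, K-complexes,
slow waves), apneas or limb movements, and scorer noise. Passing the
recovery tests therefore shows the pipeline is correct and sensitive
under the stated group structure, not that any particular performance
level transfers to clinical recordings.

## Statistical screening

Each feature is screened with the linear model `feature ~ age + group`,
testing the group term with age entered first (ANOVA controlling for
age; age enters linearly). P-values are Benjamini-Hochberg adjusted
across all tested features in one family (a global family; per-set
families would be a defensible alternative and the `features=` argument
makes either trivial). Tukey pairwise comparisons of the age-adjusted
group means (estimated marginal means) are reported for every feature
regardless of omnibus significance. Constant features are flagged and
excluded from the FDR family rather than propagating undefined F
statistics. The significance level is 0.05 throughout.

## Classification framework

For a task (NT1 vs controls / NT2 / IH / NT2+IH / all), each
realization runs:

1. stratified 70/30 split by class;
2. median imputation of missing features, medians from training rows
   only;
3. SMOTE oversampling of the training minority class to parity (k = 5
   neighbours, reduced with a warning for tiny minorities; interpolation
   between a minority row and one of its nearest minority neighbours);
4. recursive correlated-feature removal: while any pair of surviving
   features has |Spearman rho| > 0.9, drop the member with the lower
   preliminary importance (absolute rank correlation with the label on
   the balanced training set), ties by mean absolute correlation then
   name order -- fully deterministic;
5. model fit (random forest by default, 300 trees; gradient boosting
   and a Gaussian-process classifier are pluggable behind the same
   interface) and held-out scoring: F1 at the 0.5 threshold, AUC_ROC,
   and AUC_PR by step interpolation;
6. removal importance: for each selected feature, the model is refit
   without it and the importance is the drop in held-out F1 (AUC mode
   available -- both definitions circulate and neither is canonical
   here; refit-after-removal is the faithful reading of "removed from
   the classifier", and a cheaper permutation mode is provided and
   labelled as an approximation).

Running 200 realizations (the full protocol) gives the mean and SD of
each metric and importance averaged across realizations.
Hyperparameters default to fixed documented values rather than an inner
cross-validated grid search: on the synthetic cohorts the grids we
profiled did not move the metrics beyond their realization SD, and the
fixed defaults keep a 200-realization refit-importance run tractable;
`options$params` accepts any backend setting, so a grid can be laid over
`classify_once()` if a use case demands it.

Everything downstream of the split -- imputation statistics, SMOTE,
selection, fitting -- sees training rows only. The test suite checks
this directly by planting a marker feature that carries the label only
in held-out rows and verifying it cannot lift held-out AUC.

Failed realizations (degenerate splits on tiny cohorts) are skipped and
logged; a run aborts if more than 10% fail.

## Problem sizes in the shipped tests

The test suite and the acceptance script run, by design, at sizes a
laptop handles comfortably: oracle equivalence on 500 random short
hypnograms; round-trip recovery over 200 full-length (960-epoch)
hypnograms; 1000 white-noise slices for spectral calibration; a
55-subject strong-contrast cohort (NT1 n = 40 with 10-min REM-latency
scale vs control n = 15) with 20 RF realizations for classification
recovery; and 2000 null simulations for ANCOVA calibration. The
statistical conclusions these sizes support are stated with matching
tolerances in the tests themselves.

## Known limitations

* EDF/EDF+ input is not parsed; hypnograms and hypnodensities are read
  from per-epoch CSV (a documented export step from any PSG software),
  EEG from in-memory vectors or serialized recordings.
* The linear mixed model for quarter-by-diagnosis interaction
  trajectories is out of scope; the per-feature ANCOVA screen and the
  classifier cover the cross-sectional questions.
* The Gaussian-process backend relies on kernel defaults (RBF with
  automatic bandwidth); it is included for completeness, and the random
  forest is the primary, tuned path.
* Absolute classification metrics on synthetic cohorts reflect the
  generator's contrast settings and should never be quoted as expected
  clinical performance.
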