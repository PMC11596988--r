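# quartersleep

Time-resolved polysomnography (PSG) features and classification for
central disorders of hypersomnolence.

Narcolepsy type 1 (NT1) is hard to separate from narcolepsy type 2
(NT2) and idiopathic hypersomnia (IH) on symptoms alone, but its
nocturnal sleep is distinctive: early REM onset, fragmented sleep with
rising N1 across the night, and mixed sleep/wake states.
`quartersleep` turns an overnight recording into five interpretable
feature sets -- computed whole-night and per quarter-night over the
window from persistent sleep onset (first 5 min of continuous sleep) to
the final sleep epoch -- and measures how well they separate NT1 from
other groups with a resampled, class-balanced classifier.

**Feature sets** (320 features total):

* whole-night sleep metrics (8): stage proportions πs (s ∈ {W, N1, N2,
  N3, R}, Σπs = 1), total sleep time, stage shift index
  (changes/hour), REM-onset latency;
* quarter-night sleep metrics (28): the same per quarter Q1..Q4;
* transition matrices (100): row-conditional P(s → s′) per quarter,
  diagonal included;
* qEEG (120): stage-conditional multitaper relative band power
  (δ 0.5–4, θ 4–8, α 8–12, σ 12–16, β 16–30, γ 30–47 Hz), mean over
  artifact-free 2-s slices, P(band)/P(0.5–47 Hz);
* hypnodensity (64): per-quarter means of stage-probability marginals
  p(s), pairwise mixtures p(s)·p(s′), and entropy −Σ p log p.

Around the extractors: a stratified-70/30, SMOTE-balanced,
correlation-pruned classification loop (random forest primary; XGBoost
and Gaussian process pluggable) with refit-after-removal feature
importance; an age-controlled per-feature ANOVA screen with
Benjamini–Hochberg FDR and Tukey pairwise contrasts; and a synthetic
cohort generator (quarter-specific Markov chains, spectrally shaped
EEG, Dirichlet hypnodensities) that emulates the NT1/NT2/IH/control
group structure so the whole pipeline is testable end to end.

See `vignettes/quartersleep-methods.Rmd` for the model, parameter and
design details.

## Worked example

```r
library(quartersleep)

# simulate a labelled cohort with a strong NT1 contrast and extract
# all 320 features
pr <- default_profiles()
pr$NT1$rem_latency_scale <- 10      # very short REM latency in NT1
cfg <- cohort_config(n = c(NT1 = 25, control = 10), profiles = pr)
tab <- simulate_feature_table(cfg, seed = 7)

# age-controlled screening with FDR
scr <- ancova_by_feature(tab, features = c("REMonSet", "SSI", "N1-Q4"))
scr$stats

# resampled classification with removal importance
run <- run_realizations(tab, "nt1_vs_control", model = "rf",
                        n_realizations = 10, seed = 7)
run$summary
head(importance_table(run)[, c("feature", "mean_drop", "n_selected",
                               "n_top", "rank")], 3)
```

Output from this exact script:

```
   feature        F            p        p_adj significant excluded
1 REMonSet 49.21848 5.952456e-08 1.785737e-07        TRUE    FALSE
2      SSI  9.59202 4.047614e-03 4.047614e-03        TRUE    FALSE
3    N1-Q4 17.88249 1.834074e-04 2.751112e-04        TRUE    FALSE

   metric      mean         sd
1      F1 0.9255952 0.07451288
2 AUC_ROC 0.9619048 0.06659104
3  AUC_PR 0.9857426 0.02517630

   feature  mean_drop n_selected n_top rank
1 REMonSet 0.02571429         10     0    1
2 N2toW-Q2 0.02571429         10     0    2
3   N3R-Q3 0.02571429         10     0    3
```

Reading it: all three screened features differ between synthetic NT1
and controls after age adjustment (FDR-adjusted p < 0.05); the
classifier separates the groups well (mean held-out AUC 0.96); and
REM-onset latency ranks first by mean F1 drop when removed -- tied
with two other features at this toy size, where the F1 granularity of
an 11-subject held-out set quantises the drops.  At the acceptance
cohort size (NT1 n = 40 vs control n = 15, 20 realizations) REM-onset
latency's mean drop (0.037) is about four times the runner-up's, the
qualitative signature the package is built to detect.  (Metrics on
synthetic cohorts reflect the generator's contrast settings, not
expected clinical performance.)

A command-line front end over the same functions is installed at
`inst/cli/quartersleep.R` with `simulate`, `extract`, `stats` and
`classify` subcommands.

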