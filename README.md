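# relbeta

Relative EEG beta-band power as a biomarker of biological sex: a tested,
end-to-end pipeline for cohort-level validation.

## The scientific problem

Deep-learning work on clinical EEG suggested that the beta band carries
enough information to identify biological sex, and that a simple,
interpretable feature — **relative beta-band power** — captures most of it.
Per channel,

    rel_beta = P[12, 25) / ( P[0.5, 4) + P[4, 8) + P[8, 12) + P[12, 25) )

i.e. beta power divided by the summed power of the δ, θ, α and β bands.
Validating such a biomarker on a new cohort requires a full chain: artifact
cleaning of multichannel resting-state EEG, band-power features, and
classifier evaluation that is honest about class imbalance and overfitting.
`relbeta` implements that chain for the standard 19-channel 10–20 montage,
for anyone who wants to test spectral sex dimorphism (or any analogous
band-power group effect) on their own or simulated data:

* **Synthetic cohorts** (`sim_config()`, `simulate_cohort()`,
  `inject_artifacts()`): seeded 19-channel EEG with 1/f background, alpha
  and beta oscillations, a log-normal per-subject beta amplitude factor
  whose sex effect is set so any monotone beta feature has analytic AUC
  `pnorm(effect_size / sqrt(2))`, paired pre/post sessions with a
  configurable subject-level correlation, and ground-truth-logged flat
  channels, decorrelated channels and bursts.
* **PREP-style cleaning** (`preprocess()`): resampling, edge trims,
  flat-channel and low-correlation channel detection, artifact subspace
  reconstruction (PCA per sliding window, 5× robust calibration scale),
  bad-window rejection (strict more-than-4-bad-channels rule),
  spherical-spline interpolation, average re-reference, 40 Hz FIR low-pass
  — with a full audit trail (`cleaning_report`).
* **Features** (`compute_psd()`, `relative_beta()`,
  `build_feature_table()`): Welch spectra (2 s Hann, 50% overlap) that
  never bridge rejected windows; per-channel and channel-mean relative (or
  absolute) beta power joined to subject metadata.
* **Evaluation** (`evaluate_models()`, `roc_curve()`, `auc()`,
  `constrained_max_accuracy()`, `balanced_subsample_mean_roc()`,
  `loocv_scores()`, `rank_select_channels()`): univariate and 19-channel
  logistic models; ROC/AUC with the minority class (men) as positive;
  maximum accuracy constrained to TPR > 50% and FPR < 50%; sex-balanced
  40+40 subsampling averaged over 100 ROC curves; leave-one-out validation
  with in-fold feature selection.
* **Group statistics** (`wilcoxon_ranksum()`, `bonferroni()`,
  `electrodewise_sex_tests()`, `paired_ttest()`,
  `channel_session_correlations()`, `misclassification_overlap()`).

## Worked example

A small simulated cohort through the whole chain (24 subjects, 90 s
recordings; seeds make this reproducible):

```r
library(relbeta)

cfg <- sim_config(n_subjects = 24, n_female = 14, duration_s = 90, seed = 42)
co  <- simulate_cohort(cfg)
clean <- lapply(list(pre = co$pre, post = co$post), function(recs)
  lapply(recs, function(r) preprocess(r)$recording))
tab <- build_feature_table(clean, co$metadata)
pre <- tab[tab$session == "pre", ]

fem <- pre$sex == "female"
mean(pre$mean_relative_beta[fem])   # 0.269
mean(pre$mean_relative_beta[!fem])  # 0.221

wilcoxon_ranksum(pre$mean_relative_beta[fem], pre$mean_relative_beta[!fem])
#> <test_result> Wilcoxon rank-sum (normal approximation):
#>   statistic = 97, p = 0.1207 (n = 14+10)

fit    <- fit_logistic(pre$mean_relative_beta, as.numeric(pre$sex == "male"))
scores <- predict(fit, pre$mean_relative_beta)
auc(roc_curve(scores, pre$sex))                    # 0.693
constrained_max_accuracy(scores, pre$sex)$accuracy # 58.3 (%)

channel_session_correlations(tab)$mean_feature$r   # 0.929
```

Reading the output: women's mean relative beta sits above men's (0.269 vs
0.221), in the direction the generator encodes; at n = 24 the rank-sum test
is not yet significant (p = 0.12) — at the default cohort size of 134 the
same effect rejects at p < 0.001. The univariate logistic model separates
the sexes with AUC 0.69 (the analytic target for the default effect size is
0.75; small-n noise accounts for the gap), the best threshold obeying the
TPR > 50% / FPR < 50% constraint classifies 58% of subjects correctly, and
the mean feature is strongly correlated across the paired sessions
(r = 0.93), reflecting the configured subject-level stability (0.88).

The six-cell evaluation grid (mean/all-channels × in-sample/balanced plus
leave-one-out rows) comes from `evaluate_models(tab)`.

## Command line

A thin CLI over the same functions ships in `inst/cli/relbeta.R`
(`simulate`, `clean`, `features`, `evaluate`, `stats`), reading/writing
EDF, CSV and JSON.

See `vignettes/relbeta-methods.Rmd` for the model, the open design choices
and the limits of what a green test establishes.
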