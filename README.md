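# plvdx

Diagnostic modelling of cognitive impairment in epilepsy from EEG
phase-locking-value (PLV) connectivity and clinical features.

Cognitive impairment is a common comorbidity in people with epilepsy,
and screening for it with cognitive scales is vulnerable to subjective
factors.  `plvdx` implements an objective alternative end to end, for
clinical-neurophysiology researchers: it reads 19-channel 10–20-montage
scalp EEG from EDF, extracts band-wise phase-synchronization features,
combines them with an encoded clinical history, screens features by
Fisher score, and evaluates two boosted ensemble classifiers
(AdaBoost–SVM and GBDT) under stratified five-fold cross-validation,
alongside the group-comparison statistics such cohort studies report.

## The core quantity

For two leads with instantaneous phase difference θ(t, n) at time t in
epoch n (phases from the Hilbert-transform analytic signal of
narrowband data), the phase-locking value over N epochs is

    PLV(t) = (1/N) | Σₙ exp(j θ(t, n)) |

averaged over the epoch interior to give one number per channel pair
and band: 1 for a perfectly constant phase relation, 0 in expectation
for none.  Recordings are band-passed into delta (1–4 Hz), theta
(4–7 Hz), alpha (8–13 Hz) and beta (14–30 Hz); the 19-lead montage
yields 171 pairs per band, 684 PLV features, and with 23 encoded
clinical features a 707-column subject table.  Features are ranked by
the two-class Fisher score

    F_j = Σₖ nₖ (μ_jk − μ_j)² / ( Σₖ nₖ σ²_jk + ε )

and the top-k columns feed the classifiers.

A built-in synthetic cohort generator produces phase-coupled
multichannel EEG (von Mises per-epoch phase jitter, 1/f background)
and clinical tables with known ground truth; its calibration law is
E[PLV] = I₁(κ)/I₀(κ).  See the methods vignette
(`vignettes/plv-diagnostics.Rmd`) for the model, design choices and
limitations.

## Worked example

```r
library(plvdx)

cfg      <- cohort_config(n_con = 20, n_ci = 20, seed = 1)
cohort   <- generate_plv_cohort(cfg, n_epochs = 200)
ranking  <- fisher_score(cohort$table)
head(ranking)
#> <fisher_ranking> 6 features; top 6:
#>   rank     feature     score
#> 1    1 theta_C4-P3 0.9432227
#> 2    2 theta_F3-F8 0.8155053
#> 3    3 theta_F4-F7 0.7540636
#> 4    4 theta_T5-T6 0.5538497
#> 5    5 delta_T3-F3 0.2961696
#> 6    6 theta_C4-F4 0.2945601

selected <- select_top_k(ranking, cohort$table, 150)
cross_validate(selected, algorithm = "gbdt", seed = 1)
#> <cv_report> gbdt, 5-fold CV (seed 1)
#>        accuracy precision recall     f1   auc
#> fold 1    1.000      1.00   1.00 1.0000 1.000
#> fold 2    0.875      0.80   1.00 0.8889 0.875
#> fold 3    0.875      1.00   0.75 0.8571 1.000
#> fold 4    0.875      0.80   1.00 0.8889 1.000
#> fold 5    0.750      0.75   0.75 0.7500 0.875
#> mean      0.875      0.87   0.90 0.8770 0.950
```

The cohort implants five theta-band couplings with expected PLV 0.65
(CI) versus 0.35 (CON): four of the five implanted pairs top the
Fisher ranking (the fifth sits just below), and the GBDT recovers the
group contrast with 87.5% mean cross-validated accuracy and mean AUC
0.95 on held-out folds.  `run_pipeline()` repeats this for all three
feature views (clinical / PLV / combined) and both algorithms, writing
ranking, comparison and per-fold metric files plus a reproducible run
log.

For real data, `read_edf()` loads a recording into the canonical
montage and `extract_plv_features()` runs broadband filtering, 6-s
epoching, optional amplitude-based epoch rejection, band
decomposition, Hilbert phase and PLV vectorization in one call.

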