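# jipcluster

Baseline phenotyping of early (rheumatoid) arthritis patients by their
**joint involvement pattern (JIP)**, from routinely collected first-visit
data: age and sex, RF/ACPA serology, blood profile (hemoglobin, hematocrit,
leukocytes, thrombocytes), ESR, and tender/swollen indicators over a
bilateral 44-joint atlas.

The package is aimed at biostatisticians and clinical researchers who want
a tested, reproducible implementation of this stratification pipeline and a
calibrated simulator to study its behaviour:

1. **Preprocessing** — Yeo-Johnson normalisation of numerics (maximum
   likelihood λ per variable), log transform for ESR, one-hot encoding of
   categoricals; all parameters frozen for reuse on external cohorts.
2. **Patient embedding** — a multimodal autoencoder (encoder
   100 → 128 → 64 → 8) with a Bernoulli head for categorical columns and a
   Gaussian head for numeric columns, trained by Adam with early stopping
   on an 80/20 split.
3. **Clustering** — PhenoGraph-style community detection: Euclidean kNN
   graph (k = 30), Jaccard edge weights
   `|N(i) ∩ N(j)| / |N(i) ∪ N(j)|`, and a from-scratch Louvain modularity
   optimiser.
4. **Validation** — bootstrap co-clustering stability with Hungarian
   community matching, projection of replication cohorts through the frozen
   transform and encoder, LISI physician-mixing diagnostics, Kaplan-Meier /
   log-rank / Cox (Efron ties, Schoenfeld checks) survival analysis of
   methotrexate failure, LOCF DAS44 < 1.6 remission, and proportional-odds
   ordinal models of Krenn synovitis grades with Wald and Kruskal-Wallis /
   Dunn tests.
5. **Interpretation** — gradient-boosted surrogate classifier with
   Monte-Carlo permutation Shapley attributions (exact enumeration oracle
   for small feature sets), per-cluster baseline profiles and
   joint-prevalence matrices for mannequin displays.
6. **Synthetic cohorts** — a first-class generator
   (`default_calibration()`, `generate_cohort()`, `generate_outcomes()`,
   `generate_synovium()`) that plants four phenotypes — JIP-foot,
   JIP-oligo, JIP-hand, JIP-poly — with published baseline marginals,
   one-year methotrexate failure fractions 27/23/16/30%, remission
   fractions 44.3/47.4/55.7/38.5%, and severe Krenn-grade contrasts.

The methods vignette (`vignettes/jip-phenotyping.Rmd`) documents the model,
every tunable parameter with its default and rationale, what the generator
does and does not emulate, and known limitations — including the honest one
that modularity-based community detection resolves the generator's discrete
serology substructure as extra communities, so four-cluster recovery of the
planted labels plateaus near ARI 0.6–0.7 while stability, calibration and
outcome statistics meet their targets.

## Worked example

```r
library(jipcluster)

cfg    <- default_calibration(n_patients = 400L)
cohort <- generate_cohort(cfg, seed = 7)
cohort <- generate_outcomes(cohort, cfg, seed = 8)

fit <- jip_fit(cohort, seed = 7)
print(fit)
#> Joint-involvement-pattern cluster model
#>   400 patients, embedding dim 8, kNN k = 30
#>   5 communities, modularity Q = 0.6245
#> cluster
#>   1   2   3   4   5
#>  94 106  36  62 102
```

The planted phenotypes profile like a baseline-characteristics table
(`cluster_profile(cohort, cohort$data$true_label)`):

```
    cluster   n age_mean acpa_pct              esr            sjc        tjc
1  JIP-poly  69     54.1     40.6   22.4 (12.2-39)     15 (12-18) 22 (19-25)
2  JIP-foot 109     53.8     63.3 20.2 (11.5-36.8)       8 (6-10)  11 (9-13)
3 JIP-oligo 120     60.6     64.2 20.8 (11.3-37.1)        2 (1-3)  2.5 (1-4)
4  JIP-hand 102     67.4     35.3 38.1 (18.1-61.6) 10.5 (8.25-13)  12 (9-14)
```

JIP-hand is the elderly, seronegative, hand-dominant group; JIP-poly the
high-burden group. Their simulated methotrexate prognosis differs the way
the calibration plants it — with JIP-poly as reference:

```r
sv <- mtx_survival(cohort)
sv$group <- factor(sv$group,
                   levels = c("JIP-poly", "JIP-hand", "JIP-foot", "JIP-oligo"))
cox_fit(sv, ~ group)
#> Cox proportional hazards fit (efron ties): 400 subjects, 236 events
#>                   coef    HR lower95 upper95        p
#> groupJIP-hand  -0.8266 0.438   0.289   0.661 8.82e-05
#> groupJIP-foot  -0.1403 0.869   0.607   1.244 4.44e-01
#> groupJIP-oligo -0.3684 0.692   0.484   0.989 4.34e-02
```

At this small n the hand-vs-poly hazard ratio (0.438, 95% CI 0.29–0.66)
scatters around the planted ratio log(0.84)/log(0.70) = 0.489. Stability,
projection of new cohorts (`predict(fit, new_cohort)`), Shapley
attributions (`fit_surrogate()`, `shapley_attributions()`) and synovitis
models (`generate_synovium()`, `ordinal_fit()`) follow the same pattern;
see the vignette.

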