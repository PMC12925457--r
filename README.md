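# seroatlas

Proteome-scale autoantibody profiling for antigen-array serology, built for
studies that screen patient sera against thousands of protein fragments —
planar arrays (dual IgG/IgA channels, pooled sera) for discovery and
suspension bead arrays (per-individual MFI readouts) for targeted screens —
and then ask which autoantibodies track which clinical features.

The pipeline covers, end to end:

- **Signal conditioning** — IgA-from-IgG channel subtraction for planar
  arrays (clipped at zero), per-sample median loading correction plus
  healthy-referenced robust z scores for bead arrays, and top-titer
  candidate selection from pooled screens.
- **Seropositivity calling** — per-antigen cutoffs calibrated on healthy
  donors at a target specificity (default 0.99) using the inverted-ECDF
  quantile with strict `>` calls, plus prevalence banding (<5%, 5–10%,
  >10%) per cohort group.
- **Association atlas** — every antibody × every clinical feature:
  chi-squared (± Yates) for binary features, Mann-Whitney (exact by full
  enumeration up to combined n = 20, tie-corrected normal above) for
  continuous ones, pairwise-complete with no imputation; Ward (`ward.D2`)
  clustering of −log10 p profiles; top-6-per-cluster panels; group-median
  rankings.
- **Panel evaluation** — composite AAB+ flags (positive for ≥1 panel
  antigen), odds ratios with Altman standard errors
  (SE = √(1/a + 1/b + 1/c + 1/d), Haldane 0.5 correction for zero cells),
  PPV/NPV, logistic-regression ROC/AUC, and first-event assignment with
  HB-cancer/death pooling.
- **Repertoire dynamics** — per-sample autoantigen diversity counts and
  four-way seroconversion classification between paired timepoints.
- **Deconvolution** — Human-Protein-Atlas-style four-fold
  expression-specificity categories (tissue enriched / group enriched /
  tissue enhanced / low specificity / not detected), hypergeometric
  tissue overrepresentation among autoantigen targets, and
  tissue-restricted co-expression.
- **Synthetic cohorts** — a generator with recorded ground truth
  (log-normal baselines, planted low-prevalence seropositivity, antigen
  co-occurrence blocks, planted feature associations, longitudinal
  conversion, serum pooling), since individual-level serology data are
  typically access-restricted.

Everything is tibble-first and pipe-friendly; results come with
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate a bead-array cohort with two co-occurring antibody blocks — one
driving a binary feature (cirrhosis, OR 6), one shifting a continuous
feature (alkaline phosphatase, +1 SD) — then run the full screen:

```r
library(seroatlas)
library(dplyr)

cfg <- sim_config(
  n_cases = 400, n_healthy = 100, n_disease_controls = 60, n_antigens = 60,
  planted_prevalence = 0.08,
  planted_associations = list(
    planted_association(1:4, "cirrhosis", "binary", effect = 6, baseline = 0.25),
    planted_association(5:8, "ap", "continuous", effect = 1)),
  antigen_blocks = list(list(antigens = 1:4, prevalence = 0.1),
                        list(antigens = 5:8, prevalence = 0.1)),
  seed = 2024)
cohort <- generate_cohort(cfg)

hd      <- cohort$annotation |> filter(group == "HD") |> pull(sample)
normed  <- normalize_signals(cohort$signals, reference = hd)
cutoffs <- fit_cutoffs(normed[normed$sample %in% hd, ], specificity = 0.99)
psc     <- cohort$annotation |> filter(group == "PSC") |> pull(sample)
calls   <- call_positivity(normed[normed$sample %in% psc, ], cutoffs)

atlas <- build_atlas(calls, cohort$annotation,
                     c(cirrhosis = "binary", ap = "continuous"))
atlas |> filter(tested) |> arrange(p) |> select(antigen, feature, test, p, q) |> head(5)
#>   antigen feature   test                p            q
#> 1 ag0003  cirrhosis chi-square   5.44e-10 0.0000000327
#> 2 ag0001  cirrhosis chi-square   1.17e- 9 0.0000000352
#> 3 ag0004  cirrhosis chi-square   8.93e- 8 0.00000179
#> 4 ag0002  cirrhosis chi-square   3.36e- 6 0.0000504
#> 5 ag0007  ap        Mann-Whitney 4.70e- 6 0.000102
```

All eight planted antigens surface at the top of their features. Build a
panel from the cirrhosis-linked cluster and evaluate it:

```r
clusters  <- cluster_atlas(atlas, 4)
panel     <- top_per_cluster(atlas, clusters, "cirrhosis")
panel_ags <- panel |> filter(cluster == cluster[antigen == "ag0001"]) |> pull(antigen)

flag <- composite_flag(calls, panel_ags)
ann  <- cohort$annotation[match(calls$sample, cohort$annotation$sample), ]
tab  <- contingency_table(flag$aab_pos, ann$cirrhosis)
glance(odds_ratio_ci(tab))
#>      or             p     n corrected defined
#> 1  6.19 0.00000000946   400 FALSE     TRUE
predictive_values(tab)
#>     ppv   npv
#> 1 0.685 0.740
roc_auc(flag$aab_pos, ann$cirrhosis)
#> Logistic-regression ROC: AUC = 0.615 (127 positives, 273 negatives)
```

The AAB+ flag recovers the planted odds ratio (6.19 against a configured 6);
PPV/NPV and AUC are modest, as expected for a low-prevalence composite flag —
these depict association strength, not a clinical classifier. Pool-design
arithmetic is available directly:

```r
min_detectable_prevalence(8, 1)
#> [1] 12.5
```

`autoplot(atlas)` draws the association bubble grid,
`autoplot(prevalence_table(calls, ann))` the prevalence-band heatmap, and
`autoplot(roc_auc(...))` the ROC curve.

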