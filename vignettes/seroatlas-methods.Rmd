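---
title: "Methods: from antigen-array signals to an autoantibody atlas"
author: "seroatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from antigen-array signals to an autoantibody atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seroatlas implements a proteome-scale autoantibody profiling pipeline for
antigen-array serology: planar arrays read in two detection channels (IgG and
IgA) on pooled sera for discovery, and suspension bead arrays read per
individual for a targeted screen. This vignette is the package's account of
the statistical machinery: the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic cohorts do and do
not establish about real data.

## Signal conditioning

**Planar channel subtraction.** Planar arrays are scanned after the anti-IgA
and again after the anti-IgG detection step, so the IgG scan contains the IgA
signal. `subtract_channel()` computes the element-wise difference
IgG − IgA and clips it at zero. Clipping is a deliberate convention:
reactivity is non-negative, and a negative difference carries no information
beyond "no IgG-specific reactivity". Subtraction is applied before any
normalization; the order is documented rather than assumed, because the two
operations do not commute.

**Bead normalization.** Raw median fluorescence intensities (MFI, arbitrary
units) carry per-sample scale (total immunoglobulin load, dilution accuracy)
and per-antigen scale (coupling efficiency, fragment immunogenicity). The
default method in `normalize_signals()` removes both:

1. each sample row is divided by its median signal across antigens
   (probe-loading correction; the output is invariant to multiplying a row
   by any positive constant);
2. each antigen is converted to a robust z score against an explicitly
   supplied healthy reference population:
   \(z = (x - \tilde{x}_{HD}) / (1.4826\,\mathrm{MAD}_{HD})\).

The median/MAD pair resists the heavy right tail that genuine rare
reactivities produce; a mean/SD pair would let a few true positives inflate
the scale and hide themselves. When the reference MAD is zero, the scale
falls back to IQR/1.349; when both are zero the antigen carries no
information in the reference and is flagged (`noninformative` attribute) and
zeroed rather than producing infinities. The method is recorded in output
metadata and can be switched off (`method = "none"`), since different
laboratories run different in-house schemes.

**Candidate selection.** On pooled planar data, `select_top_reactive()`
takes the `k` highest-signal antigens per pool per channel and returns the
union. Within-pool ties break lexicographically by antigen id so reruns and
reimplementations select identical panels.

## Seropositivity calling

Cutoffs are calibrated on healthy donors only, at a target specificity
(default 0.99, configurable; `fit_cutoffs()`). Two conventions are fixed
because they silently change call rates if left to a library default:

- the cutoff is the *inverted empirical CDF* quantile (type 1), the smallest
  observed value such that the fraction of healthy training values strictly
  above it is at most \(1-\text{specificity}\);
- a call is positive only if the signal is *strictly greater* than the
  cutoff (`call_positivity()`), so ties at the cutoff never create
  positives.

Both choices are conservative and make the training-set specificity
guarantee exact by construction. Cutoffs must be fit on the same
representation (raw or normalized, same healthy reference) that is later
called; the cutoff table carries its provenance to make leakage visible.
`prevalence_table()` bands per-group prevalences into <5%, 5–10% and >10%
with left-closed boundaries.

A reference-cohort size consideration: with \(n\) training donors the type-1
cutoff at specificity 0.99 is an upper order statistic, and the true
exceedance probability of a fresh donor is approximately
Beta\((n-\lceil 0.99n\rceil+1,\ \lceil 0.99n\rceil)\)-distributed around
0.01. For the held-out calibration study shipped with the package we size
the training reference at 1,000 donors: a beta-binomial coverage calculation
shows that the exact binomial 99% envelope on 50 held-out donors then covers
the per-antigen false-positive count for ≈99.7% of antigens, whereas
a reference of ~100 donors concentrates too little (≈96–98% coverage).
With small real-world references the same check is expected to flag a few
percent of antigens; that is a property of order statistics, not a defect of
the calibration.

## The association atlas

Every antigen is screened against every clinical feature on
pairwise-complete data — missing clinical values are dropped per pair, never
imputed.

- **Binary features** use Pearson's chi-squared test on the 2×2 table of
  call × feature, with Yates continuity correction by default
  (`correct = TRUE`, matching the default of the standard R test). The
  correction is deliberately conservative; for type-I *calibration* studies
  the uncorrected statistic is the right object (the Yates null rejection
  rate sits visibly below the nominal level), so the correction is
  configurable and both variants are tested. Tables with a zero margin are
  flagged `degenerate margin` rather than tested.
- **Continuous features** use the two-sided Mann-Whitney U test. For
  combined \(n \le 20\) the null distribution of U is enumerated over all
  \(\binom{n}{n_1}\) group assignments of the observed (possibly tied)
  values; the two-sided p is twice the smaller tail, capped at 1. Above 20,
  the tie-corrected normal approximation is used without continuity
  correction. Arms smaller than 3 non-missing values are reported
  untestable instead of yielding unstable p values. Effects are summarized
  as per-arm medians and their fold change.

Severe-event analyses compare event-proximal samples with inclusion samples
of event-free patients (`event_analysis_samples()`); patients with several
events are assigned the earliest one, with cholangiocarcinoma, gallbladder
and hepatocellular carcinoma pooled as "HB cancer" and other causes as
"death" (`assign_event()`; same-date ties resolved transplantation > HB
cancer > death, flagged).

Raw p values are primary — the screen is exploratory and the study design
this mirrors reported unadjusted associations — with per-feature
Benjamini-Hochberg q values attached as optional metadata.

**Clustering.** Antibodies are clustered by Ward's method (the `ward.D2`
variant on Euclidean distances) over their profiles of \(-\log_{10} p\)
across features. The feature space is a design decision: the alternative of
binary call co-occurrence across samples is provided
(`space = "cooccurrence"`). Untested cells contribute zero signal; antigens
are sorted by id before clustering so the dendrogram does not depend on
input order; the number of clusters is a parameter, not an estimate.
`top_per_cluster()` selects up to six members per cluster by smallest p,
ties again broken by antigen id. `rank_by_group_median()` implements the
median-contrast ranking used for disease-duration style questions: top-k
antigens by Mann-Whitney p, each with per-arm medians, their ratio and a
direction tag.

## Panel evaluation

`composite_flag()` marks a patient AAB+ when positive for at least one panel
antigen. Against a binary outcome, `odds_ratio_ci()` computes
\(\mathrm{OR} = ad/bc\) with the Altman log-scale standard error
\(\sqrt{1/a + 1/b + 1/c + 1/d}\), the CI \(\exp(\ln\mathrm{OR} \pm z\,SE)\),
and a two-sided normal p from \(z = \ln \mathrm{OR}/SE\). Zero cells
receive the Haldane–Anscombe 0.5 correction — the standard companion to
these formulas that keeps estimate and error finite — and tables with an
empty margin are flagged undefined rather than corrected into existence.
When no cell is zero, corrected and raw values coincide. PPV and NPV come
from the test-result margins. `roc_auc()` fits a logistic regression of the
outcome on the predictor (no interactions), sweeps thresholds over the
unique fitted probabilities and integrates trapezoidally; for a single
predictor this equals the rank AUC \(U/(n_1 n_2)\) up to orientation (a
negative slope mirrors the value around 1/2), an identity the tests assert.
ROC curves here depict association strength; they are not validated
clinical classifiers.

## Repertoire dynamics

`diversity_count()` counts recognized antigens per sample under one fixed
healthy-calibrated cutoff rule — no per-timepoint recalibration, because
longitudinal comparisons require a fixed decision rule.
`classify_conversion()` maps paired calls to four categories (0→1
seropositive conversion, 1→0 seronegative conversion, 1→1 stable positive,
0→0 stable negative); the categories partition patients × antigens exactly.
`summarize_conversions()` reports the fraction of patients with at least
one seropositive conversion and category proportions over two labelled
denominators — all slots, and positive-involved slots only — because the
natural denominator for repertoire displays is ambiguous and both readings
are defensible. For patients with more than two samples, the earliest and
the event-proximal sample are the intended pair.

## Tissue and cell-type deconvolution

`classify_specificity()` applies four-fold expression-specificity rules to
a genes × tissues TPM table, with precedence: *not detected* (below 1 TPM
everywhere; the floor mirrors the convention of public expression atlases
and is configurable) → *tissue enriched* (≥4× every other tissue) →
*group enriched* (a group of 2–5 tissues, or 2–10 cell types, with mean
≥4× every outside tissue) → *tissue enhanced* (≥4× the mean of all other
tissues) → *low tissue specificity*. The group search only examines the
top-k expressing tissues for each size k: if any size-k group qualifies its
mean is at most that of the top-k set, and every tissue outside the top-k
set is no larger than the largest tissue outside the qualifying group, so
the top-k set qualifies too — the restriction is exact, not heuristic, and
the test suite verifies it against exhaustive subset enumeration. The
smallest qualifying group is reported. A tissue whose competitors are all
zero counts as infinitely enriched.

`overrepresentation()` tests whether tissue-elevated genes (enriched, group
enriched or enhanced in the tissue) are overrepresented among autoantigens
with a one-sided hypergeometric test; the statistic is a design decision
(the finding it mirrors was stated without one), and the background
universe defaults to all assayed antigens rather than all genes — the
fragments that could have been detected are the correct null universe for
an array screen. `tissue_coexpression()` correlates an anchor autoantigen
with partners across samples of one tissue, Spearman by default to match
the rank-based treatment of expression data elsewhere in the pipeline.

## The synthetic-data generator

Restricted individual-level data cannot ship with an analysis pipeline, so
every stage is exercised on synthetic cohorts with recorded ground truth
(`sim_config()`, `generate_cohort()`).

- **Baseline reactivity** is log-normal per antigen. The true
  healthy-donor MFI distribution of any given assay is not published; the
  log-normal stand-in is chosen because it reproduces the operative
  feature — a heavy right tail that makes high-specificity cutoffs
  non-trivial — and it is flagged as a stand-in, not an estimate. Default
  log-scale locations spread over [4, 6] and scales over [0.3, 0.6], giving
  median signals of roughly 50–400 units with realistic tail-weight
  heterogeneity across antigens.
- **Seropositivity** is planted in cases at low prevalence (default 0.08,
  inside the 5–10% band typical of disease-associated autoantibodies), as a
  multiplicative shift of the latent titer (default fold 8, roughly an
  order of magnitude above background, as strong reactivities are); healthy
  donors and disease controls draw from baseline only.
- **Clinical features** with planted dependence are generated conditionally
  on the *true latent* seropositive state, not the called state, so cutoff
  errors propagate into association tests exactly as they would in a real
  screen. Binary features use a configured odds ratio on a configurable
  baseline rate (default 0.3); continuous features a location shift in SD
  units.
- **Co-occurrence blocks** (`antigen_blocks`) let sets of antigens share
  one latent state per case, emulating antibody clusters with a common
  driver; this is what makes cluster-recovery experiments meaningful.
- **Longitudinal pairs** flip each negative call positive with `pos` rate
  and each positive negative with `neg` rate (defaults 0.1 and 0.05 per
  antigen-slot over the sampling interval — seropositive conversions
  dominate seroreversions in progressive disease). The flip stream is
  drawn from an operation-specific seed offset so it is independent of
  whatever the same seed generated upstream.
- **Pooling** is the arithmetic mean of member signals: one positive donor
  at titer T in a pool of g donors with baseline b yields b + (T−b)/g,
  which is exactly the dilution arithmetic that makes 100/g% the minimum
  detectable within-group prevalence (`min_detectable_prevalence(8, 1)` =
  12.5%). Pool sizes of 6–8 are enforced in the design config.
- **Expression atlases** are generated so that the four-fold rules recover
  each planted label exactly, with safety margins around every boundary so
  jitter never flips a category.

The generator fixes every artifact bit-for-bit given the seed. What it does
*not* emulate: plate/batch structure beyond an optional additive offset,
antigen cross-reactivity, assay saturation at high titer, drift between
longitudinal assay runs, and correlation between clinical features. Passing
parameter-recovery tests therefore shows the pipeline is correct and
calibrated under its stated model, not that the model captures every
failure mode of real arrays.

## Verification at scale

The shipped checks run at these problem sizes (chosen to make the
statistical tolerances tight while staying desk-sized): classifier
equivalence against exhaustive subset enumeration on 10,000 random rows
with up to 8 tissues; analytic statistics (chi-squared ± Yates, exact
Mann-Whitney by full enumeration at combined n ≤ 10, Altman OR/SE/CI,
hypergeometric tails) against direct evaluations on 1,000 random instances
each at relative error ≤ 1e-9; held-out cutoff calibration over 500
antigens × 1,000 training + 50 held-out donors; type-I control on a null
cohort of 400 cases, 100 healthy donors, 200 antigens and 10 features
(uncorrected statistic, see above); planted-association recovery
(prevalence 0.1, OR 6, n = 400) over 100 replicates; three-block cluster
recovery (mean adjusted Rand over 20 seeds); conversion-rate recovery
within exact binomial 99% intervals; and ROC identities on 1,000 random
instances. `scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

Cutoffs are global, not per-plate; mixture-model or parametric cutoffs are
out of scope. Association tests are unadjusted two-group screens — no
covariates, no interactions, no survival modelling. The cluster count is a
parameter. The bead normalization is one defensible scheme among several,
which is why it is explicit, recorded in metadata and optional.
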