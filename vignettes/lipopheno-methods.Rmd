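---
title: "Lipoprotein phenotyping of sepsis cohorts: methods and design notes"
author: "LipoPheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipoprotein phenotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipoPheno)
```

## The scientific problem

Sepsis outcomes are heterogeneous: most patients recover rapidly, but a
substantial minority develop chronic critical illness (CCI) or die
early. Enrollment lipoprotein levels (HDL-C, LDL-C, total cholesterol,
ApoA-I, PON-1 activity) are depressed in the patients who do badly, and
this depletion co-occurs with endothelial dysfunction (ICAM-1,
E-selectin), inflammation, and organ failure. `LipoPheno` operationalizes
this as an unsupervised phenotyping problem: find patient clusters
driven by the joint biomarker profile, characterize them with a
statistical signature, and test whether the same structure re-appears
in an independent cohort.

## Outcome adjudication

The primary outcome partitions every complete record into exactly one
of three categories:

* **early death** — in-hospital death within 14 days of sepsis onset
  (`death_day` is 1-based, so "within two weeks" is `death_day <= 14`);
* **CCI** — ICU stay strictly beyond 14 days with continued organ
  dysfunction at day 14, or an ICU stay of at most 14 days ending in
  discharge to long-term acute care, another hospital, or hospice;
* **rapid recovery** — everything else.

Two edge rules matter. First, the ICU-stay comparator is exposed
(`cciComparator`, default `">"`): descriptions of CCI vary between "more
than" and "at least" 14 days, and the operational outcome definition we
follow uses the strict form. Second, a stay beyond the threshold with
*unknown* day-14 organ-dysfunction status raises an error rather than
silently defaulting — no quantitative day-14 dysfunction rule (e.g. a
SOFA cutoff) is assumed, because none is defined for this adjudication;
the boolean must be supplied.

LDL-C may be derived from the lipid panel by the Friedewald relation
`LDL = TC − HDL − TG/5` (mg/dL). The estimate is invalid at high
triglycerides; the conventional bound TG < 400 mg/dL is enforced and
can be disabled (`tgLimit = Inf`).

## Derivation clustering

Patients are compared by the Spearman correlation of their z-scored
feature profiles, `d(i, j) = 1 − ρ_s(z_i, z_j) ∈ [0, 2]`. The
correlation is computed **between patients** across features
(sample-wise), not between features: clusters are sets of patients, and
the companion heatmap clusters samples only. Average ranks handle ties;
a patient whose profile is entirely tied has no defined rank
correlation and is reported by name as an error.

Agglomeration uses Ward's minimum-variance criterion via the
Lance–Williams recurrence in the squared-update convention,

d(k, i∪j)² = [(nᵢ+nₖ)·d(k,i)² + (nⱼ+nₖ)·d(k,j)² − nₖ·d(i,j)²] / (nᵢ+nⱼ+nₖ),

applied directly to the 1 − ρ dissimilarities. On Euclidean input this
is exactly Ward; on a correlation-based dissimilarity it is the usual
heuristic generalization, and we follow the stated combination
deliberately. Merges are fully deterministic: among equal-cost pairs the
one with the lowest smaller creation index (leaves in input order, then
merge order) wins, so reruns need no seed. Pipeline entry points
additionally sort patients by id first, which makes the whole derivation
invariant to input row order. The implementation is checked in the test
suite against a naive re-scan agglomerator that recomputes every
cluster distance from scratch each step via the closed form
d(A,B)² = 2·n_A·n_B/(n_A+n_B) · (S_AB/(n_A n_B) − T_A/n_A² − T_B/n_B²),
and against `hclust(method = "ward.D2")` heights.

The number of clusters is fixed at k = 2 for phenotyping, justified by
two diagnostics computed from the same tree (`elbowCurve()`): the
within-cluster sum of squares per k, and the Calinski–Harabasz score
CH(k) = [B/(k−1)] / [W/(n−k)] on the z-matrix. On synthetic cohorts
with planted two-phenotype structure, the CH curve peaks at k = 2.

Because dendrogram left/right is a layout accident, semantic labels are
anchored on data: the cluster with the lower median of the anchor
feature (HDL-C by default, the top discriminating feature) becomes the
*Hypolipoprotein* cluster. Tied medians fall back to the lower mean and
then the lower cluster index, with a warning.

## Preprocessing and its transfer parameters

Missing cells are median-imputed (`imputeMedian()`), fitting the
medians on the cohort itself during derivation. Scaling
(`fitScaler()` / `applyScaler()`) is the ordinary z-score with sample
SD (denominator n − 1); a constant feature gets σ = 0, is flagged, and
maps to z = 0 so it is cluster-neutral rather than NaN-propagating.
The fitted means, SDs and medians, together with the outlier cap c
(default 3 SD), form `ScalerParams` and travel with the signature.

Three protocol choices are configurable because the replication
protocol specifies them only on one side:

* **Capping**: outliers are capped at ±3 SD during replication
  projection; the derivation default is *no* cap (matching a literal
  reading of the protocol), switchable via `capDerivation`.
* **Imputation source**: when projecting, missing replication cells are
  filled with the *derivation* medians by default (a pure transfer
  protocol); `imputeSource = "replication"` uses the target cohort's
  own medians instead.
* **Eligibility**: patients missing strictly more than
  `floor(0.20 · |F|)` signature features are excluded with a recorded
  reason (with 15 features: more than 3 missing).

Projecting a cohort through its own signature with matched settings
(no cap, no eligibility exclusions) reproduces the derivation z-matrix
and labels bit-for-bit; the test suite asserts this identity.

## The cluster signature and replication

`deriveSignature()` runs a two-sided t-test per feature between the two
clusters. Welch's unequal-variance form is the default — the cluster
variances of skewed biomarkers differ visibly — with Student's form
available for sensitivity analysis (`testVariant = "student"`).
Features are tiered at p < 0.05 (`*`) and p < 0.0001 (`**`), tiers are
nested by construction, and *all* tested features are retained: the
replication protocol re-uses the signature's feature list as a fixed
panel, so discarding non-significant features would change the
transfer. "Top discriminating features" are ranked by |t| (ties broken
alphabetically); |t| is the natural magnitude of the signature's own
tests, though note that on raw measurement scales the t of a heavily
separated log-normal feature saturates with its multiplicative CV.
Degenerate features (both clusters constant) get t = 0, p = 1 rather
than an error.

`projectReplication()` chains eligibility filter → median imputation →
z-normalization with the derivation parameters → ±3 SD cap → Spearman
distance → Ward → 2-cut → anchor labelling.
`signatureConcordance()` then re-tests each feature between the
projected clusters and flags significance at the Bonferroni threshold
0.05/|F| — always the exact quotient (0.05/15 = 0.00333…), never a
rounded presentation value — and records per-feature direction
agreement (equal, nonzero signs of normo − hypo).

## Outcome statistics

* `groupCompare()`: continuous variables by Wilcoxon rank-sum (exact
  when both arms have ≤ 25 observations and no ties; otherwise the
  normal approximation with tie and continuity correction); categorical
  by Pearson chi-square, with Fisher's exact test when any *observed*
  cell is below 5 — the literal convention followed here; the
  expected-count trigger is available via `fisherOn = "expected"`. The
  Bonferroni threshold 0.05/m is attached with m from the analysis
  family (e.g. 47 enrollment comparisons, 15 signature features).
* `spearmanMatrix()`: pairwise-complete Spearman ρ between a lipid
  panel and endothelial/inflammatory markers, p from the
  t-approximation, per-pair n recorded; pairs with n < 3 are NA.
* `clusterOutcomeTable()`: counts and percentages
  (100·count/cluster-n, one decimal) of the three outcomes plus 28-day
  mortality per cluster.
* `lassoSelect()`: L1-penalized logistic regression of CCI-or-early-
  death (vs rapid recovery) on a standardized candidate design,
  complete-case, with ApoA-I log-transformed; λ by 10-fold
  cross-validated deviance (seeded, minimum rule — the protocol leaves
  folds, loss and rule open, so these conventional choices are fixed in
  config); the selected set is refit unpenalized to yield per-unit odds
  ratios with 95% Wald intervals. Quasi-separation is flagged and fewer
  than 10 events triggers a warning. At λ = 0 the fit agrees with the
  IRLS MLE to 10⁻⁶ (tested).
* `rocAuc()` / `compareSignatureAuc()`: AUC by the Mann–Whitney
  pair-counting estimator (midranks; ties count ½), curve by threshold
  sweep from (0,0) to (1,1). The primary ROC predictor for the
  signature is *binary* cluster membership (hypo = 1) — whether the
  original analysis used a binary or a continuous score is not stated,
  and the binary reading is the conservative one; SOFA and APACHE II
  are compared on the same patients.

## The synthetic cohort generator

No patient-level data are public, so the generator *is* the test bed.
Its defaults are calibrated once to the published summary statistics
and then frozen:

* **Phenotype prevalence**: 58/168 (derivation; 172 enrolled, 168
  clustered) and 26/86 (replication).
* **Biomarkers** are log-normal per phenotype — enrollment cytokine and
  lipoprotein tables are strongly right-skewed — with log-location
  log(median) and log-scale IQR/1.349 taken from the per-cluster
  medians and quartiles of each cohort; simulated per-phenotype medians
  therefore match the published cluster medians up to sampling noise
  (tested to 15% at n = 4000). Vitals and composite scores with roughly
  symmetric summaries use the raw scale.
* **SOFA components** are ordinal 0–4, produced by thresholding a
  latent Gaussian severity (cutpoints 0, 0.7, 1.5, 2.2) whose
  per-phenotype shift reproduces the published component medians; total
  SOFA is the component sum, never drawn independently. Binary
  covariates (ventilation, vasopressors, statins) threshold their own
  latents at phenotype-specific rates.
* **Correlation**: one latent correlation matrix shared by both
  phenotypes, sign-constrained — lipoproteins positive with one
  another and with blood pressure, negative with endothelial,
  inflammatory and severity features; triglycerides side with the
  endothelial block — at magnitude 0.4 (0.2–0.3 for the weaker,
  discretionary links). The printed sign pattern is not exactly
  positive semidefinite, so it is projected once to the nearest
  correlation matrix (`Matrix::nearPD`); the repaired matrix is the
  stored configuration and the one empirical correlations converge to
  (tested conditionally on phenotype, since between-phenotype
  separation inflates marginal correlations).
* **Outcomes** are drawn per patient from the phenotype-conditional
  probability triples implied by the published cluster-outcome counts
  (derivation hypo 26/58, 23/58, 9/58; normo 87/110, 16/110, 7/110;
  replication hypo 12/26, 6/26, 8/26; normo 33/60, 19/60, 8/60), and
  the clinical fields (ICU days, death day, disposition, day-14
  dysfunction) are synthesized so that re-adjudication reproduces the
  drawn label exactly. 28-day mortality is forced TRUE for early
  deaths and drawn for the rest to hit the per-phenotype marginal
  (counts over cluster denominators). One published derivation
  mortality percentage pair is inconsistent with its cluster
  denominators; the counts are authoritative here.
* **Missingness** is MCAR per cell (default 5%; only missing *counts*
  are published, no mechanism), never touching total SOFA or the
  adjudication fields.

`scaleSeparation(config, f)` scales the whole between-phenotype
contrast about its midpoint: f = 0 is the null model (no planted
structure — downstream ARI against the latent labels is ≈ 0), and the
planted-structure test condition used throughout the suite scales the
contrast until the weakest lipoprotein reaches a standardized
separation of 2 SD ("separation ≥ 2 SD on the lipid block"). We read
that condition as a single global dial on the planted contrast,
quantified on the phenotype-defining lipid block, rather than an
amplification of the lipids alone: the phenotype is a whole-profile
construct, and the sign-constrained ±0.4 within-phenotype correlation
noise is strong enough that a five-feature contrast alone does not
determine profile-rank geometry.

**What passing tests do and do not show.** The generator emulates
cross-sectional enrollment panels with two latent phenotypes, MCAR
missingness, and a single global correlation structure. Real cohorts
have informative missingness, batch and assay effects, more than two
(or no discrete) latent classes, treatment feedback and longitudinal
dynamics — none of which are modelled. Recovery of planted structure
therefore validates the *pipeline machinery* (distances, linkage,
transfer arithmetic, selection), not the clinical claim itself; and the
published data-dependent headline numbers (AUC ≈ 0.75, specific odds
ratios, cohort medians) are properties of the unavailable study data
that synthetic cohorts can only track directionally.

## Problem sizes and numerical conventions

The test suite works at the study's own scale: derivation cohorts of
n = 172 (and n = 200 for recovery sweeps over 10 seeds), replication
cohorts of n = 86, n = 10⁴ draws for generator self-consistency
(Goodman 99% simultaneous multinomial intervals), 50 seeded runs of
n = 400 for LASSO recovery of a planted OR = 0.2/SD protective effect,
and 200 random instances (n ≤ 12) for the Ward oracle. Further
conventions: distances are clamped to [0, 2] against rounding; merge
heights are validated non-decreasing with 10⁻⁸ slack; W = 0 in the CH
score returns +Inf with a warning; signature JSON uses 17 significant
digits so serialization round-trips are lossless; all tie-breaks
(merge pairs, anchor medians, feature ranking) are deterministic.

## Known limitations

Ward on 1 − ρ dissimilarities is heuristic (documented above);
profile-rank distances discard per-feature magnitude information by
construction; the CH diagnostic assumes Euclidean geometry on the
z-matrix while the clustering itself is rank-based; median imputation
understates variance and the eligibility rule is a blunt missingness
guard; LASSO selection frequencies are not post-selection-valid
p-values, and the unpenalized refit inherits selection noise. These
mirror the underlying protocol; the package exposes flags where a
defensible alternative exists rather than silently deviating.
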