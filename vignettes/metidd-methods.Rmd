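---
title: "Methods: CSF metabolomic modelling of CNS inflammatory demyelinating diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF metabolomic modelling of CNS inflammatory demyelinating diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metidd` implements a complete analysis pipeline for GC-MS metabolite
profiles of cerebrospinal fluid (CSF) in CNS inflammatory demyelinating
diseases (IDDs): multiple sclerosis (MS), neuromyelitis optica spectrum
disorder (NMOSD) and idiopathic transverse myelitis (ITM), against healthy
controls. This vignette describes the statistical methods, the tunable
parameters, the synthetic cohort generator used to exercise the pipeline,
and the numerical and design choices a maintainer should know about.

## Pipeline overview

```{r, eval = FALSE}
library(metidd)
cohort <- generate_cohort(reference_design(seed = 1))
norm   <- sum_normalize(cohort$matrix)
filt   <- occurrence_filter(norm, cohort$samples, min_frac = 0.5)
imp    <- impute_missing(filt, "half_min")
sc     <- autoscale(imp, transform = "log", scaling = "uv")
labels <- cohort$samples$group

stats  <- contrast_stats(norm, cohort$samples, "CTRL", "MS")
model  <- fit_opls(sc$matrix, labels, a_pred = 2, a_orth = 1)
panel  <- build_panel(sc$matrix, labels,
                      vip_ranking(sc$matrix, labels)[1:8], n_boot = 500)
screen <- merged_gradual_screen(imp, cohort$samples)
net    <- build_network(cohort$metabolites, cutoff = 0.7)
```

The same sequence, with all stage outputs and a provenance record, runs via
`run_pipeline(default_config(seed = 1))`.

## Preprocessing

**Sum normalization.** Each sample's present values are divided by the
sample's summed intensity and rescaled by the cohort-median total, which
keeps the original magnitude. This removes per-sample technical loading
variation (injection volume, derivatization efficiency). It is idempotent
and leaves missing cells missing. Note the compositional consequence: a
metabolite that dominates the total partially cancels its own fold change
under this transform; interpretation of fold changes is always relative to
the summed identified signal.

**Occurrence filter.** A metabolite is kept when its presence fraction
reaches `min_frac` (default 0.5) in at least one study-design group.
Presence means a non-missing cell; a measured zero counts as present
because GC-MS non-detects are censored values, not zeros.

**Imputation.** Missing cells are replaced by half the metabolite's minimum
present value (`half_min`), the usual limit-of-detection surrogate.
`none` is available for the univariate stage, which tolerates missing
values; the latent-variable stage requires complete data. Half-minimum
imputation is deliberately simple and is known to create low outliers for
tightly dispersed metabolites; this matters for the generator design below.

**Scaling.** Natural-log transform followed by unit-variance (UV)
autoscaling is the default for all latent-variable modelling, matching the
de-facto default of the commercial chemometrics software this style of
analysis is usually run in. Pareto scaling and raw-scale analysis are
available (`scaling = "pareto"`, `transform = "none"`); the configuration
is recorded in the scaling state and in pipeline provenance, because the
choice is consequential and rarely reported. Univariate fold changes and
t-tests always run on the sum-normalized, unlogged scale, so a fold change
is a plain ratio of group mean abundances.

## Univariate contrasts

Two-sided pooled-variance (Student) t-tests per metabolite, with
`fold_change = mean(case) / mean(reference)`; contrasts may pool groups
(e.g. all diseases vs control). Welch's correction is available by flag but
off by default, and no multiple-testing correction is applied by default
(a Benjamini-Hochberg option exists and the output records the choice);
both defaults mirror the original analysis style that the pipeline
reproduces. Fold changes use arithmetic means; the arithmetic/geometric
choice is ambiguous in the field, and arithmetic is what a ratio of group
means in a table usually is. Metabolites with fewer than two present values
on a side are flagged untestable and never enter significant sets.

## Latent-variable models

**PLS-DA.** NIPALS PLS2 on the scaled matrix against one-hot class dummies
that are centered *and unit-variance scaled*. Scaling the dummy block is
the standard chemometric construction and is essential with unbalanced
classes: with 12 controls among 145 samples, a centered-only control dummy
carries ~7% of the response variance and control-vs-rest discriminators
could never reach the top of any importance ranking. Convergence is
declared when the score vector changes by less than 1e-10 (relative), with
a 2000-iteration cap; non-convergence reports the component index.
Component signs follow the convention that the largest-|weight| variable is
positive, making score plots reproducible across runs.

**OPLS(-DA).** Trygg-Wold orthogonal filtering: each orthogonal weight is
the current PLS loading minus its projection onto the column space of
`X'Y`. Because `X'Y` is invariant under orthogonal deflation, one
orthonormal basis serves every round, and every orthogonal score has
exactly zero sample correlation with every response column (asserted to
1e-8 in the tests, in practice ~1e-15). With zero orthogonal components
the model coincides with PLS-DA.

**Cross-validated Q².** `Q² = 1 - PRESS/SSY` accumulated over stratified
folds (7 by default), with centering/scaling re-estimated inside each
training fold. Fold assignment is deterministic: samples sorted by ID,
shuffled by a per-stratum seed, dealt cyclically — so Q² is invariant to
row order. Predictive component counts can be chosen by the conventional
rule of adding components while Q² improves by more than 0.01
(`choose_ncomp()`); the multi-class models in the pipeline default to
`number of classes - 1` predictive components (the discriminant
dimensionality), which is deterministic and avoids re-running CV inside
every ranking.

**VIP.** `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` over
predictive components; the mean squared VIP is exactly 1 (algebraic
identity, asserted to 1e-8). VIP ties are broken by ascending metabolite
name for determinism.

**p(corr).** The Pearson correlation between the single predictive score
and each scaled column; the coordinate of S- and SUS-plots. Restricted to
one-predictive-component models by construction.

## Biomarker panels and ROC

AUC is the Mann-Whitney statistic with midranks
(`P(score+ > score-) + 0.5 P(tie)`), unflipped — the positive class is
expected to score high. Panels are scored by a single latent component: a
one-component two-class PLS-DA per one-vs-rest contrast, oriented so the
positive class has the higher mean. One model per contrast (rather than a
single shared component) is the default because per-contrast AUCs need
per-contrast orientation; the 4-class first component remains accessible
through `fit_plsda()` directly.

**Panel size sweep.** For each panel size k, the top-k VIP features are
scored and the four one-vs-rest AUCs averaged. Two estimation details
matter and are defaults for a reason:

* scores are computed *out-of-fold* (7-fold CV): in-sample single-component
  scores become monotonically more optimistic as features are added, so an
  in-sample sweep has no optimum at all;
* the VIP ranking is re-computed *inside every training fold*: ranking on
  the full cohort lets chance-correlated features earn both their rank and
  their apparent discrimination from the same samples, which also inflates
  the curve past the true optimum.

Fold-assignment noise on the resulting flat-topped curve is of the same
order as the 0.005 plateau tolerance, so the sweep averages `n_rep`
repeated cross-validations (2 in the pipeline default; 8 in the recovery
experiments). The reported plateau is every k within 0.005 of the maximum
mean AUC.

**Bootstrap confidence intervals.** Percentile intervals from
class-stratified resampling (default 500 replicates), deterministic given
a seed. Percentile (not BCa) matches the convention of the web tools this
analysis style uses; BCa could be added behind the same interface. At the
panel sample sizes used here the percentile interval's empirical coverage
of a true AUC of 0.8 sits at the lower edge of its nominal 95% (the tests
assert 90–99% over 200 simulations), which is the known behaviour of the
percentile method.

**Joint clinical model.** Clinical covariates (EDSS, OCB, CSF protein by
default) are appended as columns: numeric covariates autoscaled like
metabolites, the binary OCB centered but *not* variance-scaled (unit
variance would hand a rare binary indicator outsized leverage). Samples
missing a selected covariate are dropped with a reported count. VIP is
re-ranked on the augmented model and the top 10 features form the joint
panel. The reported reference composition is available as
`panel_joint_reference()`.

## Remission-relapse screening (SUS)

Two one-predictive-component OPLS-DA models share the control class:
control vs remission and control vs relapse, fitted on pre-treatment
samples only (a `pre_treatment` annotation flag is honored when present
and warned about when absent). Each metabolite is placed by its p(corr) in
the two models; the predictive score is oriented so the disease class has
the positive mean.

Region classification is a deterministic function of the two coordinates
and three thresholds (`c_contrib = 0.3`, `c_axis = 0.1`, `c_diag = 0.1`):
axis-hugging points are status-specific, the diagonal band is shared
response, and points above the diagonal band (`y > x + c_diag`, `x >
c_axis`) are the gradual control < remission < relapse signature. The
thresholds are configuration values, not literature values — the original
style of analysis classifies these plots visually — and every output
records the thresholds used. The defaults were fixed once, by the
requirement that the designed synthetic gradient structure is recovered,
and are not tuned per dataset.

The merged screen pools statuses across diseases, takes the
`shared_up_gradual` region, and keeps metabolites confirmed univariately
(relapse vs remission, p < 0.05 and fold change > 1). K-means on
per-metabolite z-scored profiles (pattern, not magnitude; 20 seeded
restarts, best within-cluster sum of squares) confirms the monotone
pattern cluster-wise. Heatmap ordering uses average-linkage clustering of
1 - Spearman rank correlation; constant profiles (undefined correlation)
are flagged and placed last.

## Chemical-similarity network and pathway statistics

Tanimoto similarity `|A∩B| / |A∪B|` over binary substructure fingerprints;
pairs at or above the connectivity cutoff (default 0.7) become edges, and
reaction-pair (substrate-product) edges are overlaid regardless of
similarity, with pairs satisfying both marked `both`. Fingerprints and
reaction pairs are *input data* (the generator ships a synthetic
catalogue; real catalogues can be supplied in the same schema) — nothing
is fetched from chemical databases at run time, which keeps every analysis
reproducible offline. Networks export as SIF plus a node-attribute TSV in
deterministic lexicographic order; node annotation maps significant
contrast results to up/down colours and |log2 fold change| sizes (the
log2 magnitude makes 0.5x and 2x changes the same size, which a linear
scale would not).

Pathway over-representation is the upper-tail hypergeometric probability
`P(X >= k)`; pathway impact is the sum of relative betweenness
centralities of the hit metabolites over the pathway total, on the pathway
graph formed by reaction pairs restricted to pathway members (0 when the
pathway carries no centrality at all). No multiple-testing correction is
applied across pathways by default, mirroring the analysis style being
reproduced; a BH flag exists.

## The synthetic cohort generator

`reference_design()` encodes the study conditions the pipeline assumes:
145 samples (12 control, 54 MS, 49 NMOSD, 30 ITM; remission/relapse splits
near-proportional per disease, with 57 remission and 61 relapse samples
flagged pre-treatment), 85 metabolites in the published chemical-class
proportions, and every published per-disease fold-change effect (the
pooled-disease column is not imposed; it emerges from the pairwise
effects, and its published values are consistent with that arithmetic).

Abundances are log-normal per metabolite with multiplicative group and
status effects — the natural model for fold-change semantics and
non-negative peak heights. Further structure, each piece chosen once and
frozen:

* **Dispersions.** Per-metabolite log-scale standard deviations. For
  non-panel reference metabolites the dispersion is back-solved from the
  published p-value and group sizes (t statistic → standardized effect →
  sigma), so each carries exactly the evidence strength its table entry
  reports. The 8 reported panel metabolites get tighter dispersions than
  their printed p alone would imply: the defining property of the reported
  panel is that it was the top of the VIP ranking, so panel-SNR primacy is
  treated as a designed condition. This is the one deliberate departure
  from the printed univariate statistics (most visible for lactic acid),
  and it is what makes the panel-recovery experiments meaningful.
* **Abundance anchors.** A handful of high-abundance, homeostatically
  stable CSF metabolites (glucose, urea, creatinine, myo-inositol, citrate,
  glycerol) dominate the summed chromatogram intensity. None of them
  carries a designed effect: sum normalization cancels a dominant
  metabolite's own fold change through compositional closure, so anchoring
  the total on effect-free metabolites keeps designed fold changes
  recoverable on the normalized scale.
* **Technical loading.** A per-sample log-normal loading factor
  (sd 0.2) that sum normalization removes exactly — the reason the
  normalization stage exists.
* **Missingness.** Missing-not-at-random censoring: base rate 0.005 per
  cell, doubled below an absolute limit-of-detection quantile (default:
  the 25th percentile of all cells), with metabolites that carry designed
  structure drawing baselines above the censoring region. The base rate is
  deliberately low: half-minimum imputation turns even one or two missing
  cells into extreme low outliers for a tightly dispersed metabolite,
  which would contradict the designed signal-to-noise ordering;
  identified, curated GC-MS metabolites are in practice reliably detected.
* **Status gradients.** Sixteen metabolites — thirteen fatty acids plus
  beta-hydroxybutyrate, oxoproline and putrescine — carry multiplicative
  remission/relapse effects (1.35x / 2.20x) producing the monotone
  control < remission < relapse signature; lactate and fumarate carry a
  milder version (1.08x / 1.22x) of the same relapse elevation.
* **Clinical coupling.** EDSS is a rounded, clamped latent score: disease
  base 3.5, +1.2 in relapse, plus signed contributions from standardized
  log-abundances (monoacylglycerols positive, ethanolamine / threose /
  1,5-anhydroglucitol negative) and unit noise; controls are 0. OCB is
  Bernoulli with MS enrichment (0.85 vs 0.2–0.3 elsewhere, 0.05 in
  controls); CSF protein and white-cell counts are log-normal with disease
  and relapse elevation; IgG index is MS-elevated.

**What the generator does not emulate** — and therefore what passing
recovery tests do and do not show: there are no batch effects or
chromatographic drift, no unidentified signals alongside the 85 curated
metabolites, and metabolite-metabolite correlations arise only through
shared design factors (group, status, the total) rather than a realistic
biochemical covariance structure. Recovery results on this generator
demonstrate that the estimators recover the structure they are designed
for at realistic effect sizes and sample sizes; they do not certify
performance on real cohorts with correlated biochemistry and technical
artefacts.

## Numerical choices and degenerate inputs

* NIPALS convergence 1e-10 (relative score change), 2000 iterations;
  rank exhaustion and non-convergence raise errors naming the component.
* Both-sides-constant t-tests return p = 1 when means agree (and the
  smallest positive double when they disagree, keeping p in (0, 1]).
* Tanimoto similarity of two empty fingerprints is NA (reported, not an
  edge); fold change exactly 1 is never labelled up or down.
* VIP ties and SIF output are ordered lexicographically; K-means and the
  bootstrap take explicit seeds; every stochastic pipeline stage has a
  seed in its configuration, and configs without one are rejected.
* Problem sizes used by the test-suite recovery experiments: 20 cohorts of
  145 x 85 for panel and SUS recovery, 200 simulations for bootstrap
  coverage and type-I calibration, 50 random graphs (up to 8 nodes) and
  exhaustive enumeration (universes up to 12) for the combinatorial
  oracles — sizes at which the checked quantities are stable without being
  wasteful.

## Known limitations

* The published headline model statistics (R²Y = 0.597, Q² = 0.271; panel
  AUCs up to 0.991) were computed on the deposited cohort with unstated
  scaling and component counts; they are not exactly reproducible from the
  publication alone and are not asserted. The acceptance checks run the
  same estimators on the synthetic analogue instead, where the designed
  truth is known.
* The univariate stage reproduces the original uncorrected-p analysis by
  default; for new studies the BH option should be considered.
* Single-component panel scoring is linear; metabolite panels with
  strongly non-additive effects would need a different scorer behind the
  same ROC interface.
* The pathway catalogue bundled with the generator is a toy; real
  fingerprint/reaction-pair/pathway catalogues are supplied as input files
  in the documented schema.
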