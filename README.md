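# metidd

Metabolomic modelling of CNS inflammatory demyelinating diseases from
cerebrospinal fluid (CSF) GC-MS profiles.

Differential diagnosis of multiple sclerosis (MS), neuromyelitis optica
spectrum disorder (NMOSD) and idiopathic transverse myelitis (ITM) is hard:
their clinical and radiological presentation overlaps, and no single CSF
marker separates them. `metidd` implements, as a tested R package, the full
analysis chain used to mine a samples-by-metabolites CSF abundance table
for multi-metabolite biomarker panels and disease-status signatures:

* **Preprocessing** — sum-intensity normalization, per-group occurrence
  filtering (keep a metabolite detected in ≥ 50% of at least one group),
  half-minimum imputation of censored non-detects, log + unit-variance
  autoscaling with reusable scaling state.
* **Univariate contrasts** — per-metabolite Student t-tests and fold
  changes `mean(case)/mean(reference)`, for pairwise and pooled-disease
  contrasts.
* **Latent-variable models** — NIPALS PLS-DA and OPLS-DA. The orthogonal
  filter removes response-orthogonal variation exactly
  (`w_o = p − proj_{X'Y}(p)`; every orthogonal score has zero correlation
  with every response column). Cross-validated predictive ability
  `Q² = 1 − PRESS/SSY` with in-fold re-scaling; variable importance
  `VIP_j = sqrt( p · Σ_a SSY_a (w_{ja}/‖w_a‖)² / Σ_a SSY_a )` (mean square
  exactly 1); `p(corr)` loadings for S- and SUS-plots.
* **Biomarker panels** — the top-VIP metabolites are coordinately
  transformed to a single latent component (T1) per one-vs-rest contrast
  and evaluated by rank AUC (Mann–Whitney with midranks) with stratified
  percentile-bootstrap confidence intervals; a panel-size sweep with
  selection honestly re-done inside cross-validation locates the optimal
  panel size; clinical covariates (EDSS, oligoclonal bands, CSF protein)
  can join the panel.
* **Remission/relapse screening** — shared-and-unique-structures (SUS)
  coordinates from paired OPLS-DA models (control vs remission, control vs
  relapse), deterministic region classification (status-specific, shared,
  and the gradual control < remission < relapse signature), K-means
  confirmation, and a merged cross-disease relapse screen.
* **Metabolic networks** — Tanimoto fingerprint-similarity edges (cutoff
  0.7) overlaid with reaction-pair edges, SIF + node-attribute export,
  hypergeometric pathway over-representation and relative-betweenness
  pathway impact.
* **Synthetic cohorts** — `reference_design()` / `generate_cohort()`
  generate 145-sample, 85-metabolite cohorts carrying the published
  per-disease fold-change effects, fatty-acid relapse gradients and
  clinical-covariate coupling, so every stage is testable without any
  external download.

## Worked example

```r
library(metidd)

cohort <- generate_cohort(reference_design(seed = 1))
cohort$matrix
#> metab_matrix: 145 samples x 85 metabolites (74 missing cells)

norm <- sum_normalize(cohort$matrix)
filt <- occurrence_filter(norm, cohort$samples)
sc   <- autoscale(impute_missing(filt))
labels <- cohort$samples$group

cs <- contrast_stats(norm, cohort$samples, "CTRL", "MS")
subset(cs, metabolite %in% c("1-monostearin", "threose", "phenylalanine"))
#>     metabolite      p_value fold_change direction significant testable
#>        threose 5.775706e-18   0.3133962      down        TRUE     TRUE
#>  phenylalanine 2.149453e-04   0.8326785      down        TRUE     TRUE
#>  1-monostearin 1.790819e-06   1.5948087        up        TRUE     TRUE

panel <- build_panel(sc$matrix, labels,
                     vip_ranking(sc$matrix, labels)[1:8],
                     n_boot = 500, seed = 1)
panel
#> biomarker panel: threitol, threose, lactic acid, glycolic acid, inosine,
#>                  proline, 3-hydroxypropionic acid, 1-monostearin
#>   CTRL_vs_rest       AUC = 0.996
#>   ITM_vs_rest        AUC = 0.942
#>   MS_vs_rest         AUC = 0.878
#>   NMOSD_vs_rest      AUC = 0.915

screen <- merged_gradual_screen(impute_missing(filt), cohort$samples)
length(screen)
#> [1] 16
```

Reading the output: threose is strongly depleted in MS CSF (fold change
0.31) while 1-monostearin is elevated (1.59); the eight top-VIP metabolites,
combined into a single PLS component per contrast, separate controls from
patients almost perfectly (AUC 0.996) and each disease from the rest with
AUC 0.88–0.94; and 16 metabolites — predominantly saturated fatty acids —
rise monotonically from control through remission to relapse across all
three diseases.

The whole chain, including the joint clinical model, SUS screening and
network export, runs as one configured pipeline:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

which writes per-stage tables (TSV), the network (SIF), a JSON panel
report and a provenance record carrying the config hash.

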