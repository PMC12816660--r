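# convergemap

Convergent causal mapping of frontal visuospatial-attention networks in R.

Neurosurgical cohorts offer two complementary causal probes of brain
function: the permanent effect of resecting tissue, and the transient effect
of intraoperative direct electrical stimulation (DES). `convergemap`
implements the analysis pipeline that joins them for visuospatial
exploratory/selective attention (the function disrupted in hemispatial
neglect):

* **Behavioural scoring** — the Bells cancellation test (35 targets among
  280 distractors): total score (omitted targets), asymmetry score
  (left − right omissions), pre/post deltas with a worsening-positive sign
  convention, and the group statistics such studies report (split-plot
  repeated-measures ANOVA with partial η², paired *t* with Cohen's
  *d*ᶻ, Wilcoxon signed-rank with rank-biserial *r*, Spearman ρ with its
  companion *t*).
* **SVR-LSM** — multivariate lesion-symptom mapping: an RBF-kernel ε-SVR
  from binary resection masks to the behavioural score, with direct total
  lesion volume control (dTLVC), covariate residualization, voxel inclusion
  at ≥ 10 % cohort overlap, permutation-based voxelwise p-values, and
  continuum family-wise error (CFWER) cluster correction; cross-validated
  prediction accuracy and half-split reproducibility as model-quality
  indices.
* **Connectomics** — fibre-bundle-capacity (FBC, mm²) matrices from
  SIFT2-weighted streamline sets (TCK + weight files + μ sidecar), node
  strength/degree/betweenness, composite hub z-scores, consensus hubs and
  consensus top edges, and track-density imaging (TDI).
* **Disconnection modelling** — simulated postoperative tractograms by
  removing streamlines that transect the resection cavity, per-edge
  percentage disconnection, and Spearman correlation with deficit severity
  under Bonferroni correction.
* **Stimulation mapping** — scoring of the intraoperative visuospatial
  attention task (iVSAT), the eloquence rule (errors in ≥ 3 non-consecutive
  stimulated trials), the omission-position lateralisation index, 3D kernel
  density maps (PDE) of stimulation sites, and convergence overlap (Dice)
  between the PDE mask, the SVR-LSM cluster, and the TDI core.
* **Synthetic cohorts** — seeded generators that emulate the statistical
  structure of each stage (planted deficit-critical region, planted hubs and
  top edges, planted edge–deficit links, clustered stimulation sites with a
  left-hemifield bias), so the full pipeline runs and validates without any
  patient data.

## Worked example

```r
library(convergemap)

## a synthetic cohort of 60 resections on a 16^3 grid with a planted
## deficit-critical region (standardized effect 1.5 SD, noise SD 1)
spec <- synth_spec(seed = 7)
cohort <- make_lesion_cohort(spec)

fit <- svrlsm(cohort$masks, cohort$behaviour$delta_asymmetry_cont,
              covariates = cohort$behaviour[, c("age", "education", "grade")],
              config = svrlsm_config(n_permutations = 500, seed = 7))
summary(fit)
#> <svrlsm> n = 60 subjects, 599 included voxels
#>   hyperparameters: C = 1.56, sigma = 1.49, epsilon = 0.538
#>   significant voxels: 27 (critical p = 0.001996)
#>   prediction accuracy = 0.696 +/- 0.155; reproducibility r = 0.372
#>   clusters (size, peak mm):
#>  cluster size peak_x peak_y peak_z
#>        1   27      7      7      7

convergence_overlap(fit$significant_cluster_mask, cohort$planted_mask)$dice
#> [1] 0.5666667
```

The significant CFWER-corrected cluster (27 voxels, critical p = 0.002)
sits inside the planted critical region: a Dice overlap of 0.57 against the
33-voxel planted sphere, with a cross-validated prediction accuracy of 0.70.
The same `svrlsm` object answers `coef()` (voxelwise β weights), `plot()`
(mid-slice β map with the significant contour), and `print()`.

Group statistics use the same functions a reader would check by hand:

```r
partial_eta_sq(54.23, 1, 161)        # 0.252  — eta^2 partial from F(1,161)
cohens_dz_from_t(-5.272, 82)         # -0.582 — paired effect size
spearman_p_bonferroni(0.826, 15, 39)$p_adjusted   # 0.0057724
```

The whole pipeline, end to end, with one call:

```r
man <- run_pipeline(list(seed = 7))
man$report
```

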