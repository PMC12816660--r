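---
title: "Convergent causal mapping of visuospatial attention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent causal mapping of visuospatial attention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`convergemap` joins two causal probes of the frontal visuospatial-attention
system — surgical resection and intraoperative direct electrical stimulation
— into one analysis pipeline. This vignette is the package's account of the
models it fits, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data validation does
and does not establish.

## Behavioural model

The Bells cancellation test presents 35 bell targets among 280 distractors.
The *total score* is the number of omitted targets; the *asymmetry score*
is left-minus-right omissions, an index of lateralised inattention
(visuospatial neglect). Pre/post deltas are defined as `post − pre`, so a
positive delta means postoperative worsening; this orientation is what lets
the lesion-symptom model associate resected critical tissue with larger
deltas, and it fixes the one-tailed direction of the permutation test below.

Group inference uses a split-plot (mixed repeated-measures) ANOVA with time
(pre/post) within subjects and lesion hemisphere between subjects, fitted
via `aov` with an `Error(subject)` stratum. Effect sizes: partial
η² = F·df₁/(F·df₁ + df₂) for one-degree contrasts; Cohen's
*d*ᶻ = t/√n for paired contrasts; the matched-pairs rank-biserial
correlation r_rb = (W⁺ − W⁻)/(W⁺ + W⁻) from the Wilcoxon rank sums
(zero differences dropped, mid-ranks for ties, continuity-corrected normal
approximation for n > 25). How published r_rb values relate to the rank-sum
definition is not always reconstructible from a printed Z alone; the
rank-sum definition is adopted here because it is exact and
distribution-free. Spearman correlations are reported with the companion
statistic t = ρ√((n−2)/(1−ρ²)) on n − 2 degrees of freedom; perfectly
monotone pairs (|ρ| = 1) make this statistic diverge and are flagged rather
than reported.

Normative cutoffs for "pathological" scores belong to published norms that
are not distributed with this package; `classify_pathological()` therefore
requires them as configuration, and its defaults are placeholders.

## SVR-LSM

The lesion-symptom model is an ε-SVR with an RBF kernel from binary
resection masks to the (covariate-residualized) behavioural delta:

* **Inclusion.** A voxel enters the model when resected in at least 10 % of
  the cohort; "at least" is implemented as `ceiling(0.10 · n)` (n = 82
  gives a threshold of 9 subjects).
* **dTLVC.** Each subject's lesion vector is scaled by 1/√(total lesion
  volume), computed over the whole mask rather than the included columns,
  so resection size does not drive the kernel.
* **Covariates.** Age, education and tumour grade are regressed out of the
  behavioural score by OLS before fitting; lesion data are left untouched
  (a flag could extend residualization to the lesion side, but the default
  follows the more common behaviour-only convention).
* **β map.** With a nonlinear kernel there is no primal weight vector; the
  voxelwise β map is the back-projection `t(X) %*% α` of the sign-carrying
  dual coefficients, the convention of the established SVR-LSM toolboxes.

### Hyperparameters

C ∈ [1, 80] and kernel scale σ ∈ [0.1, 30] (libsvm γ = 1/(2σ²)) are
searched by a seeded random draw (log-uniform), with ε sampled
log-uniformly from the robust-sd-scaled default range
[10⁻³, 10²] · IQR(y)/1.349 used by common SVR tooling. A Bayesian
optimiser would explore the same box; a seeded random search of
`n_opt_iterations` points (default 200) keeps the dependency footprint
minimal and is fully reproducible.

Two deliberate choices depart from naive CV-loss minimisation:

1. **The CV loss is 1 − accuracy**, where accuracy is the mean out-of-fold
   Pearson correlation between predictions and scores — the model-quality
   index mapping studies report. Correlation is scale-free, so heavily
   regularized fits (whose predictions are shrunken but well-ordered) are
   not penalized for their shrinkage.
2. **A one-standard-error rule** picks, among candidates within one SE of
   the best CV loss, the most regularized one (smallest C, then largest ε).
   With hundreds of candidates and a noisy 5-fold CV estimate, the raw
   minimiser is systematically an extreme, near-interpolating fit
   (winner's curse); such fits produce heavy-tailed permutation nulls that
   destroy the power of the β-map inference without improving genuine
   prediction.

### Permutation inference and CFWER

The behavioural score is permuted (default 5000 times; the examples in
this package use 200–500 to stay desk-sized) and the full SVR is refitted
per permutation. The voxelwise one-tailed p-value is
`(1 + #{permuted β ≥ observed β})/(n + 1)` in the worsening direction
(two-tailed available by flag).

Cluster correction follows the continuum family-wise error (CFWER)
construction: every map (observed and each permutation) receives voxelwise
p-values by rank against the pooled ensemble; for each permutation map the
v-th smallest p is recorded; the critical value is the α-quantile of that
distribution, and observed voxels at or below it — additionally passing the
voxelwise threshold (default p < 0.005) — form the significant mask,
labelled into 26-connectivity clusters.

One numerical subtlety deserves its own paragraph: with a finite
permutation ensemble the v-th-smallest-p statistic is lattice-valued, and
with many more voxels than permutations nearly every map attains the
minimal p somewhere, collapsing the statistic to a point mass. Ties are
therefore broken by β magnitude, *studentized against the pooled ensemble*
so magnitudes are comparable across voxels (the studentization is monotone
per voxel and leaves the p-values themselves unchanged). The resulting
(p, −|β|) pair is effectively continuous, the α-quantile is well defined,
and the empirical family-wise error calibrates: over 100 synthetic null
cohorts (200 permutations each) the observed rate of any significant voxel
is 5 %.

Model quality is summarised by the cross-validated prediction accuracy
(mean ± sd of out-of-fold correlations) and a reproducibility index: the
correlation of β maps fitted on repeated random half-splits (default 10).
On the synthetic reference cohort the pipeline reaches accuracy ≈ 0.7 and
reproducibility ≈ 0.4; the ≈ 0.85 reproducibility reported for real
82-subject cohorts reflects the spatial smoothness and effect strength of
real resections, which the 16³ synthetic cohort deliberately does not
emulate (see *Synthetic data*).

## Connectomics on fibre bundle capacity

Streamlines (TCK format; per-streamline weights in a plain-text companion
file; the subject proportionality coefficient μ in a JSON sidecar) are
filtered to those traversing a region of interest. Each streamline is then
assigned to the node pair of its two endpoints — nearest labelled voxel
within 2 mm (configurable) — and edge (a, b) of the FBC matrix accumulates
μ·Σ weights, an estimate of the bundle's total intra-axonal
cross-sectional area in mm². Streamlines with unassignable endpoints are
excluded and counted; matrices are analysed unthresholded.

Node metrics: strength (row sum), degree (nonzero partners), and
betweenness centrality computed exactly on the length graph with edge
length 1/weight, normalized by (n−1)(n−2)/2. The inverse mapping is the
standard choice when edge weights measure capacity; the test suite holds
betweenness to an exhaustive path-enumeration oracle on graphs up to 12
nodes. Within each subject the three metrics are z-scored across nodes
(n − 1 denominator) and averaged into a composite hub score; a node is a
*consensus hub* when its composite z exceeds 1.5 in at least 50 % of
subjects (strictly greater than 1.5; "at least half" rounds up). For each
hub, its nonzero connections are z-scored per subject (self-loops excluded;
a flag switches to all partners including zeros) and a connection is a
*consensus top edge* by the same 1.5 / 50 % rule; edges are deduplicated
across hubs and classified as cortico-cortical, projection, or
transcallosal from the node table.

Track-density images accumulate weight·μ once per traversed voxel per
streamline; maps are z-scored over their nonzero support, subject z-maps
average into a population map, and the core mask is Z > 2. ROI traversal
and TDI both default to segment supersampling at quarter-voxel steps, so
coarsely sampled polylines that cross a voxel between vertices are still
caught; a vertices-only mode suits densely sampled tractograms.

## Disconnection modelling

A postoperative tractogram is simulated by removing every streamline that
transects the resection cavity (same traversal test, inverted); removal is
idempotent and monotone in the cavity. Edge-level loss is
100·(FBC_pre − FBC_post)/FBC_pre, clipped to [0, 100]; edges with zero
preoperative FBC are undefined and excluded pairwise from correlation.
Edge-wise association with deficit severity uses two-sided Spearman
correlation with the t-approximation p-value and Bonferroni correction over
`m` edges — `m` is an explicit argument, never inferred, because published
consensus-edge counts are not always internally consistent. For n = 15
patients without ties, ρ lives on the lattice 1 − 6k/3360; the printed
three-pathway p-values (0.0057724, 0.0076243, 0.018318) are reproduced from
the printed correlations by exactly this route.

## Stimulation mapping

The iVSAT presents 10 letters containing two 'H' targets; the patient reads
aloud the digit under each target. A site is *eloquent* when a missed
target occurred in at least three stimulated trials, no two adjacent in the
stimulated-trial sequence — the strict reading of "non-consecutive"; the
looser reading (not all in one run) is available by flag. The
lateralisation index of a site is the mean omitted position (1 = far left,
10 = far right); a site is *neglect-like* when all omissions fall in
positions 1–5 (a majority-rule variant exists). The hemifield boundary at
5/6 is the even split of the 10 positions.

The probability density map of eloquent sites is an isotropic Gaussian
kernel density over world coordinates, evaluated on a voxel grid; the
default 5 mm bandwidth matches the 5 mm stimulation-site spheres, and
Silverman-style alternatives can be passed explicitly. The raw map
integrates to 1 (verified to 1 % on grids extending several bandwidths
beyond the sites); a normalized-to-max variant is thresholded (default
50 % of the maximum) to delineate the highest-probability region, and
`convergence_overlap()` reports Dice and directed overlap fractions
against the SVR-LSM cluster or the TDI core.

## Synthetic data: what it emulates, and what it does not

The generators in `synth_spec()` define the validation conditions:

* **Lesion cohort** (per hemisphere n = 60, 16³ grid, 1 mm voxels):
  ellipsoidal resection blobs with semi-axes 2–5 voxels, centres
  concentrated around the grid interior; a planted spherical critical
  region (radius 2.2 voxels ≈ 33 voxels); Δ asymmetry = planted term +
  covariate terms + Gaussian noise (sd 1). The planted term is the overlap
  fraction with the critical region scaled so that its cohort sd equals
  1.5 noise-sd — "effect 1.5 SD" is the standardized magnitude of the
  planted component. Bells pre/post counts are reconstructed to be
  consistent with the integer-rounded deltas; the continuous delta is kept
  alongside for the mapping stages. Grid sizes keep a full recovery run
  (500 permutations) under a minute.
* **Connectome cohort** (20 subjects, 60 nodes on a lattice in a 32³ mm
  world): arced streamline bundles per edge (3 streamlines), a regular
  ring-lattice base topology (node degree set by the edge-density
  parameter, weight 1), five planted hubs connected everywhere at weight 3,
  two planted top edges per hub at 10× weight, 20 % weight jitter,
  per-subject μ ∈ [0.8, 1.2]. The base graph is regular on purpose: in a
  shared random topology the incidentally-central nodes would be consensus
  hubs of every subject, and a cohort without planted hubs could never be a
  null. Weights are stored as w/μ so the noise-free FBC is μ-invariant by
  construction.
* **Resection scenarios** (15 patients, noise sd 0.2): patient tractograms
  reduced to the 39 tested bundles; the three critical edges are routed
  through dedicated peripheral corridors with a wide fan, and a cavity of
  severity-scaled radius severs a graded fraction of their weight; the
  behavioural delta is 3 × (mean critical severed fraction) + noise. The
  corridor isolation is what makes the planted link identifiable — in real
  anatomy, bundles overlap and disconnection profiles correlate.
* **Stimulation sites** (40 sites, spread 3 mm, 8 trials): omission
  positions drawn left with probability 0.93; 70 % of sites satisfy the
  eloquence rule by construction (errors on stimulated trials 1, 3, 5),
  the rest violate it.

Passing these recoveries shows the machinery is correct and calibrated
under its own assumptions: Gaussian noise, geometrically simple lesions and
bundles, a single planted cause per stage. It does not show that real
resection cohorts of this size would localize with Dice ≥ 0.5, nor that
real consensus edges separate as cleanly — real data add registration
error, spatially correlated lesion anatomy, and non-Gaussian behaviour.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed through fixed substream
  offsets (folds, search, permutations, splits), so stages are reproducible
  independently of evaluation order; generators save and restore the global
  RNG state.
* Constant scores abort the SVR; constant node metrics z-score to 0 with a
  warning; hubs with fewer than three connections are skipped in top-edge
  scoring; all-zero difference vectors flag the Wilcoxon as undefined.
* ε-SVR fits whose insensitivity band swallows every residual (zero
  support vectors) predict the training mean and are excluded from
  selection through an undefined accuracy.
* Cluster labelling uses 26-connectivity; cluster peaks are reported at the
  voxel of largest studentized β in world mm.
* Half-splits that leave a constant score in either half are resampled and
  logged.

## Known limitations

* Betweenness on graphs with exactly tied path lengths depends on the
  shortest-path tie handling of the exact algorithm; the test oracle uses a
  1e-9 tolerance.
* The PDE normalization beyond scaling-to-max mirrors common practice, but
  in-house variants of the method exist whose exact normalization is not
  public; comparisons should be made on thresholded masks, not raw
  densities.
* The reproducibility index is a half-split statistic: at n = 60 its
  sampling noise is substantial, and values near published full-cohort
  figures should not be expected at desk scale.
* Registration, tractography, SIFT2 fitting and parcellation are upstream
  of this package: all inputs are assumed coregistered.
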