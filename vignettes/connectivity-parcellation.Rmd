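---
title: "Connectivity-based parcellation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpkit)
```

This vignette explains the model behind `cbpkit`, the meaning and defaults
of every important parameter, how the synthetic generators are designed to
exercise the pipeline realistically, and the numerical decisions and
limitations a user should know about. It states no empirical result beyond
what the package's test suite and `scripts/acceptance.R` compute.

## 1. The model

Connectivity-based parcellation (CBP) subdivides a brain region using only
the long-range connectivity of its voxels. The data object is a
seed-by-target matrix of streamline counts from probabilistic tractography:
row `i` is the *connectivity profile* of seed voxel `i`, the number of
sampled streamlines (out of `n_samples`, default 10000) reaching each
target voxel. `cbpkit` does not re-implement streamline propagation; it
starts from the counts (`connectivity_matrix()`), recording as metadata
whether the producer applied distance correction and a curvature threshold.

Three cleaning steps precede clustering:

* **Count thresholding** (`threshold_counts()`, default 2): cells with
  fewer streamlines than the threshold are zeroed, removing spurious
  single-streamline connections. The operation is idempotent.
* **Probability conversion** (`to_probability()`): counts divided by
  `n_samples`. Pearson correlation is invariant to this per-row scaling,
  so clustering results do not depend on which form is used; the
  conversion exists for interpretability and interoperability.
* **Target down-sampling** (`downsample_targets()`, default 3 mm bins):
  target voxels are grouped into axis-aligned physical bins (an integer
  number of native voxels per axis, floored; partial edge bins kept) and
  summed. Row totals are conserved exactly — a property the test suite
  asserts — and the profile dimension drops by roughly the bin volume.

The seed-by-seed similarity is the Pearson cross-correlation of profiles
(`cross_correlation()`). Constant profiles make correlation undefined;
they are an error by default, or dropped explicitly with
`drop_constant = TRUE` (the retained row indices are attached to the
result).

**Spectral clustering** (`spectral_parcellate()`): the affinity is the
similarity with negative entries clipped to zero (a `"shift"` option
mapping [-1, 1] to [0, 1] exists; clipping is the default because
anti-correlated voxels should not attract each other). The normalized
affinity `D^{-1/2} A D^{-1/2}` is eigendecomposed, the leading k
eigenvectors are row-normalized, and k-means (50 restarts, 100 iterations,
seeded) assigns labels. If the affinity graph splits into more connected
components than k the decomposition cannot produce a meaningful k-way cut
and the function stops with the component count. Degenerate k-means
outcomes (empty or singleton clusters) trigger up to 10 re-seeded
restarts. `parcellate_sweep()` computes the embedding once for the largest
K and reuses its leading columns for every k, so a sweep costs one
eigendecomposition.

**Group analysis** (`group_pipeline()`): per-subject similarity matrices
on a common template-space voxel set are averaged (optionally thresholded)
into a group matrix; its parcellation is the group reference. Each
subject's parcellation is relabeled to the reference by maximizing total
voxel overlap — a linear assignment problem solved exactly by a Hungarian
algorithm (`harmonize_labels()`). Voxelwise cluster frequencies across
harmonized subjects give probabilistic maps (`probabilistic_maps()`); at
every voxel the cluster frequencies plus the fraction of subjects missing
the voxel sum to one exactly. The maximum probability map
(`maximum_probability_map()`) assigns each voxel its most frequent
cluster, but only where that frequency strictly exceeds the missing
fraction (otherwise background; an `"always"` rule is available). A
synchronous 6-neighbor strict-majority filter (`smooth_mpm()`) removes
isolated misassignments without changing the foreground voxel count.
Hemispheric label consistency (`enforce_hemispheric_consistency()`)
mirrors one hemisphere's reference across the midline and harmonizes the
other to it.

**Choosing k** uses two independent families of evidence:

* *Reproducibility*: `resample_consistency()` repeatedly splits the
  cohort (split-half or leave-one-out), runs the group pipeline on each
  part for every k, and scores the agreement of the two smoothed MPMs on
  jointly assigned voxels with four indices — cluster-matched Dice (after
  internal harmonization), Cramér's V, normalized mutual information
  `2I/(H1+H2)` and variation of information `H1+H2-2I`, entropies in
  bits. The best k is where Dice/V/NMI peak and VI bottoms out.
  Complementary per-solution indices are the mean silhouette on
  `1 - similarity` (`silhouette_mean()`), the spatial continuity index
  (fraction of each cluster in its largest 6-connected component,
  `continuity_index()`), the hierarchy index between consecutive k
  (`hierarchy_index()`), and the topological distance between hemispheres
  (`topological_distance()`).
* *Dimensionality*: `connectivity_pca()` decomposes the connectivity
  matrix with seed voxels as variables and target voxels as observations,
  so a region with k distinct connectivity patterns shows k strong
  components. Three criteria count them: smallest k reaching a cumulative
  variance threshold (default 0.7; values outside the customary 70–90%
  band warn), the Kaiser rule (eigenvalues above 1, valid only for the
  standardized/correlation form, which is therefore the default), and a
  scree elbow (section 3). `recommend_k()` tabulates all three per
  subject and recommends the integer range spanned by the mean scree
  estimate, intersected with `[2, k_max]`.

### Orientation of the PCA

Treating seed voxels as the *variables* (decomposing the seed-by-seed
correlation matrix across target observations) is a deliberate modeling
decision. With the transposed orientation, profiles that sum to a fixed
streamline total are compositionally constrained, the grand-mean component
cancels, and a k-cluster region yields only k−1 strong components — the
criteria would systematically undercount. Under the chosen orientation the
planted-cohort tests recover the planted k with all three criteria.

## 2. Multi-atlas segmentation and quality control

Brain extraction in the same workflow is a multi-atlas problem: several
atlas images with manual labels are registered to a target, and their
mapped labels are fused. `cbpkit` implements the fusion and evaluation
stages; registration itself is external, with `similarity_metrics()`
(mean square difference, Pearson correlation, mutual information of a
32-bin joint histogram, in bits) and `qc_check()` guarding its quality.
QC failures warn and flag the subject for human inspection; they never
abort a run. Default thresholds — CC ≥ 0.85, MI ≥ 0.5 bits,
MSD ≤ (0.1 × intensity range)² — are experience-based toolkit defaults,
configurable per study.

Fusion only needs to act where atlases disagree: the *boundary uncertainty
mask* is the union of the mapped labels minus their intersection;
unanimous voxels are copied unchanged. `majority_vote()` labels a
disputed voxel foreground when strictly more than half the atlases say so
(exact ties resolved by `tie_rule`, default background).
`joint_label_fusion()` weights atlases per voxel to account for
*correlated* atlas errors: with `D_i = |T - I_i|^beta` (default β = 2),
the pairwise error matrix accumulated over a cubic patch (radius 2,
so 5³ voxels) is `M_ij = sum_patch D_i D_j`, the weights solve
`(M + ridge·I) w = 1` (ridge 1e-6), are normalized, and negative entries
are clipped and renormalized so the weights always form a probability
vector; the fused label is foreground when the weighted vote reaches 0.5.
A numerically singular system falls back to uniform weights (majority
voting) with a warning. When all atlas intensities are identical every
`M_ij` is equal and joint fusion reduces exactly to majority voting — one
of the reduction identities the test suite asserts.

`loo_fusion_protocol()` evaluates either fuser by leave-one-out over a
cohort: each subject in turn is the target, the rest are atlases, and the
fused mask is scored against the subject's own manual label with
`seg_score()`: Dice, specificity, sensitivity, the mean symmetric surface
distance (MASD) and maximum surface distance between 6-connectivity
boundary voxels in physical mm (anisotropic spacing supported), and the
relative volume difference with the manual volume as denominator.

## 3. Numerical decisions

* **Hungarian assignment in R.** Label harmonization needs an exact
  linear-assignment solver; `cbpkit` carries a small O(k³) potentials-based
  implementation with deterministic tie-breaking (lowest column index, so
  constant costs yield the identity). The tests verify optimality against
  exhaustive enumeration of all k! permutations for k ≤ 5.
* **Scree elbow.** Raw eigenvalue profiles end in a near-zero plunge that
  reflects the rank limit of the data, not structure, and a power curve
  fitted to that tail extrapolates meaninglessly back to the leading
  components. `k_by_scree()` therefore (a) truncates the spectrum to the
  components carrying 99% of the variance, (b) fits `lambda_j ~ a j^-b` on
  the log-log scale over the retained range as a *null model* — if it
  explains the profile (R² > 0.95) there is no elbow and the result is 1
  with attribute `no_elbow` — and (c) otherwise places the elbow at the
  largest drop between consecutive log eigenvalues (a chord-based variant
  on the log profile is available via `method = "chord"`).
* **Surface distances.** Nearest-boundary distances are computed from
  per-axis outer differences rather than the expanded
  `|a|² + |b|² − 2ab` form, which loses about eight significant digits to
  cancellation; the test oracles require agreement to 1e-9.
* **Determinism.** Every stochastic step (k-means seeding, resampling
  splits, generators) runs under an internal seed-scoping helper that
  saves and restores the caller's RNG state, so identical seeds give
  identical results and library calls never perturb a user's random
  stream.

## 4. The synthetic generators as study conditions

All quantitative statements in the tests and the acceptance script are
made on seeded synthetic data with planted ground truth; the generator
defaults *are* the study conditions.

**Planted connectivity cohorts** (`planted_cohort_spec()`,
`generate_cohort()`). The seed region is a small 3D box (default 12×5×5,
300 voxels) split into `true_k = 4` contiguous slabs along x — planted
clusters are spatially contiguous, as anatomical subregions are. Each
cluster has a prototype profile over 300 targets placing 45% of its mass
on a cluster-specific target block, 45% on a target block shared by all
clusters, and 10% uniformly. The shared block is essential for realism:
subregions of one anatomical region share much of their pathway anatomy,
so real profiles of different subregions correlate *positively*; without
the shared block, fixed-total count profiles are anti-correlated by
construction and the PCA loses one component. Each seed row perturbs its
prototype with multiplicative log-normal noise (sd 0.3 on the log scale)
and draws integer counts as one multinomial sample of `n_samples = 10000`
streamlines, giving realistic integer sparsity for the thresholding step.
Per subject, 5% of voxels flip to a random other cluster, emulating
inter-individual variability. Everything is a pure function of
`rng_seed`.

**Head phantoms** (`phantom_spec()`, `generate_atlas_cohort()`). An
ellipsoidal "brain" (semi-axes 8, 9, 7 voxels in a 24³ grid) with bright
interior (100) and dark background (20). Each subject deforms the shared
boundary with its own smooth random field (box-smoothed white noise,
sd 1 voxel in signed-distance units) and adds intensity noise (sd 5). A
subject's manual truth is its *own* jittered shape, and its intensity
follows that shape, so atlases that match a target's geometry also match
its intensities — the correlation structure joint label fusion exploits.

**Bilateral fixtures** (`bilateral_pair()`): a parcellation is mirrored
into the opposite half of a doubled grid, optionally with scrambled
labels, to exercise hemispheric harmonization and topological distance.

## 5. Limitations

* Streamline propagation, registration, and bias-field handling are out of
  scope; the package consumes their outputs.
* The phantom's signed distance to the jittered ellipsoid is approximate
  (radial scaling by the smallest semi-axis), so `boundary_jitter_sd` is
  calibrated in approximate voxel units. Because each subject's truth is
  its own jittered boundary, fused-vs-truth Dice is bounded by the
  subject's own jitter no matter how many atlases vote; the fusion
  comparison is therefore about the *direction* (joint fusion above
  majority voting) rather than absolute Dice levels.
* Joint label fusion implements the local-search radius as a configuration
  field but the default of 0 (no search) is the only exercised setting.
* The scree rule assumes the residual spectrum is roughly power-law; for
  spectra with several distinct breaks the largest log-gap may not be the
  scientifically interesting one, which is why three criteria are reported
  side by side.
* Validity indices operate on label vectors over a common voxel support;
  partial overlap between parcellations is handled by intersecting
  supports, and cluster-matched Dice is defined only when both
  parcellations have the same number of clusters.

## 6. Reproducing the analysis

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs, against the installed package: planted-cohort generation and group
parcellation at the planted k (with agreement indices against the
planting), the split-half consistency curves for k = 2..6, the three PCA
criteria per subject, the leave-one-out majority-voting vs joint-fusion
comparison over 20 phantom cohorts (paired one-sided test), and the exact
conservation residuals. The JSON output is bit-for-bit reproducible from
the seed.
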