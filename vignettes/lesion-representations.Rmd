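---
title: "Succinct lesion representations: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Succinct lesion representations: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute ischaemic stroke lesions are not arbitrary blobs: their shapes are
jointly constrained by the branching topology of the cerebral vasculature,
by where along the tree an occlusion happens, and by which occlusions come
to clinical attention. This package asks a practical question about that
structure: how much of a lesion's functional consequence can be predicted
from *succinct* descriptions of its anatomy — a single categorial label, a
point in a 2-D latent plane, or a 50-dimensional nonnegative loading
vector — compared with knowing only the patient's age and the lesion's
volume?

The pipeline has five stages:

1. **Simulation** (`cohort_spec()`, `generate_cohort()`,
   `generate_parcellation()`) — a synthetic stand-in for a registered
   clinical DWI cohort.
2. **Preprocessing** (`collapse_hemisphere()`, `build_data_matrix()`) —
   mirror right-dominant lesions onto one hemisphere, smooth with a 2 mm
   FWHM Gaussian, vectorise over the analysis mask.
3. **Representation learning** (`fit_nmf()`, `embed_2d()`, `saf_filter()`,
   `ward_cluster()`, `compute_centroids()`, `amalgamate()`) — the 50-D,
   2-D and categorial representations plus archetype centroid images.
4. **Ground truth** (`label_deficits()`) — synthetic deficit labels from a
   parcellation by a regional damage-threshold rule.
5. **Benchmark** (`run_experiment()`, `summarize_results()`,
   `anova_two_way()`) — balanced resampling, nested-CV gradient boosting,
   confidence intervals and a two-way ANOVA.

## The simulator: what it emulates and what it does not

Real lesion cohorts are unavailable without data-sharing agreements, so
the simulator plants exactly the structure the downstream stages claim to
recover. One hemisphere of an ellipsoidal brain mask is split by recursive,
jittered, axis-alternating bisection into a binary tree of **vascular
territories**: children partition their parent exactly, so territories
nest like arterial supply fields and every level partitions the
hemisphere. A lesion is a territory whose node is drawn from a depth
distribution (`node_weights`; the default places all mass on the leaves,
i.e. purely distal occlusions, giving `2^depth` recoverable archetypes),
perturbed in volume by a uniform multiplier (default ±15%), flecked with
boundary noise (default 3% of lesion voxels toggled in a 1-voxel rim), and
mirrored to the right hemisphere with probability 0.5. Ages are drawn from
a Normal(63.89, 15.91) truncated to [18, 97] years by rejection sampling —
the demographic profile of a representative acute stroke admission cohort —
and are independent of lesion anatomy, so age carries no deficit signal in
the defaults.

Deliberately absent: haemodynamics, grey/white contrast, registration
error, lesion multiplicity, and any real vascular atlas. Passing tests
therefore demonstrate that the pipeline recovers *planted hierarchical
territory structure* under noise — not that it would segment, register or
interpret clinical images correctly.

The synthetic parcellation mirrors the structure (not the content) of a
whole-brain functional parcellation with a network assignment: `n_regions`
Voronoi regions grown from random seeds tile the analysis hemisphere, and
k-means on seed locations groups them into `n_networks` spatially coherent
sub-networks. Real atlas files (NIfTI labels + region→network CSV) can be
supplied through `read_parcellation()` instead.

## Preprocessing choices

*Hemisphere collapse.* "Collapse onto one hemisphere" is implemented as
whole-image mirroring of right-dominant lesions about the midsagittal
plane (first voxel axis), not as a per-voxel union of image and mirror:
mirroring preserves each lesion as one coherent spatial pattern. Ties
(exactly balanced bilateral lesions) keep their original orientation, which
makes the operation idempotent. For odd first-axis extents the middle
plane is its own mirror image.

*Smoothing.* Separable Gaussian with `sigma = fwhm / (2 sqrt(2 ln 2))` per
axis (0.849 mm at the default 2 mm FWHM), discretised to a unit-sum kernel
of radius `ceil(4 sigma)` voxels, zero-padded at the boundary. Unit-sum
normalisation conserves total lesion mass exactly for interior-supported
inputs.

*The analysis mask.* Columns of the data matrix are the voxels of the
collapsed-hemisphere brain mask by default; passing the full grid as mask
reproduces full-grid vectorisation (at full clinical scale, a 2 mm
91×109×91 stereotactic grid, that is 902 629 columns). Zero-variance
columns are retained — NMF tolerates them and dropping them would make
column indices cohort-dependent.

## Representation learning

*NMF.* Rank-50 factorisation by Lee–Seung multiplicative updates under the
Frobenius loss, initialised with deterministic NNDSVD (zeros lifted to
`mean(X)/100` so updates can move them), stopping at `1e-5` relative
improvement or 500 iterations. The per-iteration error trace is computed
by the trace identity (no n×V reconstruction is ever formed) and is
non-increasing — a property the tests assert rather than assume. NMF
rather than PCA because the data are nonnegative occupancy patterns and a
parts-based decomposition separates territory fragments.

*t-SNE.* Always run on the NMF scores, never raw voxels. Per-point
bandwidths are calibrated by bisection until every conditional
distribution's perplexity is within 1e-3 of the target (default 30);
duplicate score rows are jittered by 1e-9 first. The layout minimises KL
divergence to a Student-t kernel by momentum gradient descent: 1000
iterations, early exaggeration ×12 for the first 250, learning rate
`max(50, n/12)`, adaptive gains, centring each step. All randomness
(initial layout, jitter) flows through the stage seed.

*Structure-aware filtering.* The published filtering algorithm lives in an
external code capsule and is not specified in detail; here it is
implemented at contract level as neighbourhood mean-shift regularisation:
for 10 iterations, each point moves fraction `mu = 0.2` toward the mean of
its neighbours within radius `r = 0.1` of the input bounding-box diagonal.
`mu = 0` is the identity; clusters separated by more than the radius are
filtered independently (their centroids are preserved exactly when a
cluster's diameter is below the radius). The operation is isolated behind
`saf_filter()` so a faithful reimplementation could be swapped in.

*Clustering and archetypes.* Ward minimum-variance clustering
(`hclust(method = "ward.D2")`) runs on the *filtered* 2-D coordinates (the
filtered layout is what the categorial representation discretises; whether
the original analysis used filtered or raw coordinates is not stated).
Archetype centroids are voxel-wise means of members' collapsed *unsmoothed
binary* masks — occupancy fractions with a direct reading as "share of
cluster members damaging this voxel". The original 30→21 pruning was an
expert judgment and thus irreproducible by definition; `amalgamate()`
replaces it with either an explicit user-supplied merge map (faithful
mode) or automated greedy merging of the centroid pair with highest Dice
overlap (binarised at 0.5) down to a target count or Dice floor. Merged
centroids are member-count-weighted means. New lesions are assigned by
maximum Dice to the binarised centroids, ties to the lowest cluster id.

## The deficit rule

A sub-network is affected iff **at least one** of its regions has at least
`threshold` (default 15%, boundary inclusive per "at least") of its voxels
lesioned. Damage is never aggregated across regions. White-matter tracts
are ordinary regions under the same rule. Parcellation and lesions are
compared on the collapsed hemisphere. The rule is monotone in the lesion
*given a fixed orientation*; because a grossly bilateral lesion can change
which hemisphere it collapses to, monotonicity is guaranteed (and tested)
for lesions whose regions are mirror-symmetric or whose growth stays in
one hemisphere.

## The benchmark

Four feature sets per subject: baseline `[age, volume]`; categorial
`[age, volume, one-hot cluster]` (one-hot, because integer codes would
impose a spurious ordering on depth-1 stumps); 2-D `[age, volume, x, y]`;
50-D the NMF scores alone (following the wording that the fourth
representation *is* the decomposition).

Per network and repeat, a balanced draw takes `min(#affected, #unaffected)`
subjects from each class without replacement — chance is exactly 50% — and
is shared across the four representations so they are compared on
identical subjects. "Iteratively trained and tested ten-fold" is read as
10 independent balanced resampling repeats with stratified 80/20
train/test splits (it is paired with "randomly resampling the dataset"),
not as 10-fold CV. The boosting machine is stagewise second-order gradient
boosting on depth-limited regression trees over quantile-binned features
(32 bins), with the binomial deviance or exponential loss, learning rate
0.1 (a conventional default; the original does not state one), no
subsampling. Hyperparameters — loss × {100, 300, 500} stages × depth
{1, 2, 3}, 18 grid points — are selected by stratified 5-fold inner CV on
mean accuracy, with the three stage counts harvested from one fit per
(loss, depth, fold); ties resolve to the first point in (loss, stages,
depth) order. Accuracy is the primary metric (balanced accuracy under the
balanced draw); AUROC is the midrank Mann–Whitney statistic and is `NA`
on a single-class test set.

Summaries are cell means with normal-approximation 95% intervals
(`±1.96 sd/sqrt(n)`, clipped to [0, 1]; a t-quantile option exists for
small n). The two-way fixed-effects ANOVA
(`metric ~ representation * network`) requires a balanced complete
design, under which the classical sums-of-squares types coincide; repeats
are treated as independent replicates within cells, and the optimism that
CV-style reuse injects into such F tests is a known, documented
simplification rather than something the package corrects.

## Default study conditions and problem sizes

The canonical experiment (`default_experiment()`) uses a 48×56×48 grid at
a nominal 4 mm spacing (the full-scale 2 mm 91×109×91 grid is supported
but not the default), n = 400 subjects, a depth-3 tree sampled at its 8
leaves, a 40-region / 6-network parcellation, 8 Ward clusters (matching
the planted archetype count, no amalgamation), and 10 balanced repeats.
At this scale the NMF stopping controls are trimmed to 200 iterations at
1e-4 relative tolerance — the factorisation's error curve is far into its
flat tail there, and the downstream embedding is insensitive to the
remaining drift. On these conditions the expected qualitative result is
the monotone enrichment ordering: baseline < categorial ≤ 2-D ≲ 50-D mean
accuracy, with the baseline well above chance only insofar as territory
sizes differ (volume carries some signal; age none by construction).

## Numerical and degenerate-input conventions

- All generators and the whole pipeline are pure functions of
  `(config, seed)`; stage seeds derive from one master seed via a fixed
  affine map (`derive_seed()`), and `run_all()` is byte-identical across
  reruns.
- NMF denominators carry an `1e-10` floor; t-SNE affinities are floored at
  `1e-12`; boosting leaf values are Newton steps with a `1e-6` ridge,
  clipped to ±10, and exponential-loss margins are clamped at ±50 inside
  the exponential.
- Empty lesions: an error for `collapse_hemisphere()` and
  `assign_lesion()` (there is nothing to orient or assign), but zero
  damage everywhere for `label_deficits()`.
- Ties: no mirror flip for balanced lesions; lowest cluster id for equal
  Dice; first grid point in (loss, stages, depth) order for equal inner-CV
  accuracy; constant scores give AUROC 0.5.

## Known limitations

- The simulator's planted clusters are far cleaner than clinical lesion
  anatomy; absolute accuracies here say nothing about attainable clinical
  accuracy, only about the *relative* information content of the
  representations under recoverable structure.
- The structure-aware filter is a contract-level interpretation of an
  external algorithm.
- The ANOVA treats resampling repeats as independent; its p-values are
  anti-conservative to an extent the package does not estimate.
- Balanced undersampling discards majority-class subjects; with very rare
  deficits the effective n per repeat can be small, and networks with no
  affected (or no unaffected) subjects cannot be benchmarked at all.
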