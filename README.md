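# lesionlatent

Succinct latent representations of ischaemic stroke lesion anatomy, and a
benchmark of how much predictive power they retain.

## The problem

A registered binary lesion mask lives in a voxel space of order 10^6
dimensions, but the anatomy of ischaemic stroke is tightly constrained by
the vascular tree: lesions are stereotyped, hierarchical, and largely
mirror-symmetric across hemispheres at the population level. This package
implements a pipeline that compresses lesion masks into three progressively
simpler representations and quantifies what each one is worth for
predicting downstream functional deficits:

- **50-D** — nonnegative matrix factorisation scores: `X ≈ W H` with
  `W, H ≥ 0`, rank k = 50, multiplicative updates under the Frobenius loss;
- **2-D** — t-SNE of the NMF scores (perplexity 30), refined by
  structure-aware neighbourhood filtering (strength mu = 0.2, radius
  r = 0.1 of the bounding-box diagonal);
- **categorial** — Ward minimum-variance clustering of the 2-D plane with
  archetype centroid images (voxel-wise occupancy fractions per cluster),
  optionally amalgamated to a smaller set of distinct archetypes;
- **baseline** — patient age and lesion volume only.

Synthetic ground-truth deficits come from a parcellation rule: a
sub-network is *affected* iff at least 15% of the voxels of at least one of
its regions are lesioned. Each representation then predicts each network's
label with gradient-boosted trees — grid loss ∈ {deviance, exponential} ×
stages ∈ {100, 300, 500} × depth ∈ {1, 2, 3}, chosen by stratified 5-fold
inner cross-validation — over 10 balanced resampling repeats (chance = 50%
by construction), summarised as means with 95% CIs and a two-way ANOVA
(representation × network).

Because clinical lesion cohorts are only available on request, the package
ships a first-class simulator: a hierarchical vascular-territory tree
(recursive jittered bisection of one hemisphere, so territories nest and
partition exactly), lesions sampled from its nodes with volume jitter and
boundary noise, truncated-normal ages (mean 63.89, sd 15.91, range 18–97),
and Voronoi parcellations grouped into spatially coherent sub-networks.

## Worked example

```r
library(lesionlatent)

## a 400-subject synthetic cohort from a depth-3 territory tree
spec   <- cohort_spec(n_subjects = 400, seed = 11)
cohort <- generate_cohort(spec)

## preprocess: collapse to one hemisphere, 2 mm FWHM smoothing, vectorise
dm <- build_data_matrix(cohort, fwhm_mm = 2)

## learn the 50-D, 2-D and categorial representations (8 archetypes)
rep <- fit_representation(dm, cohort, k = 50, n_initial = 8, n_final = 8,
                          seed = 42, nmf_max_iter = 200, nmf_tol = 1e-4)
table(rep$cluster_model$labels)

## deficit ground truth from a 40-region / 6-network parcellation
parc     <- generate_parcellation(spec$grid_shape, 40, 6, seed = 7)
deficits <- label_deficits(cohort, parc, threshold = 0.15)

## benchmark all four representations
feats   <- representation_features(cohort, rep$cluster_model,
                                   rep$embedding, rep$nmf)
results <- run_experiment(feats, deficits, n_outer = 10, seed = 42)
tapply(results$accuracy, results$representation, mean)
```

The equivalent canonical run is `default_experiment(seed = 11)`; on that
seed it prints mean balanced accuracies

```
        2d        50d   baseline categorial
 0.9891979  0.9896552  0.7695277  0.8393318
```

read as: age + volume alone predict simulated deficits at 77% balanced
accuracy (territory sizes differ, so volume is informative; chance is
50%), the 8-category cluster label raises that to 84%, and the continuous
2-D / 50-D embeddings to ~99% — the monotone enrichment ordering the
pipeline is designed to expose. `summarize_results()` adds 95% CIs per
(representation, network) cell and `anova_two_way()` tests the
representation and network main effects and their interaction.

A full run that writes every artefact (cohort NIfTI masks + manifest,
parcellation, NMF scores, 2-D coordinates, archetype NIfTI images, deficit
table, results/summary/ANOVA CSVs, JSON manifest):

```r
run_all(load_config(), out_dir = "run1")   # or: Rscript inst/cli/run-pipeline.R --seed 1 --out run1
```

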