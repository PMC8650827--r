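## Shared fixtures. The benchmark experiments are expensive, so they are
## computed once per test run and memoised here; several test files (and
## the acceptance properties) read the same objects.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Small grid for unit tests: big enough for a depth-3 territory tree.
small_grid <- c(24L, 28L, 24L)

small_spec <- function(n = 20, seed = 1, ...) {
  cohort_spec(n_subjects = n, grid_shape = small_grid, voxel_size_mm = 4,
              seed = seed, ...)
}

small_cohort <- function(n = 20, seed = 1, ...) {
  memo(sprintf("cohort_%d_%d_%s", n, seed,
               paste(deparse(substitute(list(...))), collapse = "")),
       generate_cohort(small_spec(n, seed, ...)))
}

## A lesion mask built from explicit voxel coordinates (i, j, k rows).
mask_from_ijk <- function(ijk, grid_shape = small_grid, voxel_size_mm = 4,
                          ...) {
  ijk <- matrix(ijk, ncol = 3, byrow = TRUE)
  idx <- (ijk[, 3] - 1) * grid_shape[1] * grid_shape[2] +
    (ijk[, 2] - 1) * grid_shape[1] + ijk[, 1]
  lesion_mask(idx, grid_shape, voxel_size_mm, ...)
}

## Hand-built parcellation on a bar-shaped grid for exact damage fractions.
## `regions` is a named list network_id -> list of region voxel index sets.
parcellation_from_regions <- function(regions, grid_shape, voxel_size_mm = 4) {
  label_grid <- array(0L, dim = grid_shape)
  region_ids <- integer(0)
  net_of <- integer(0)
  rid <- 0L
  for (nw in seq_along(regions)) {
    for (vox in regions[[nw]]) {
      rid <- rid + 1L
      label_grid[vox] <- rid
      region_ids <- c(region_ids, rid)
      net_of <- c(net_of, nw)
    }
  }
  structure(list(label_grid = label_grid, region_ids = region_ids,
                 region_to_network = stats::setNames(net_of, region_ids),
                 network_ids = sort(unique(net_of)),
                 voxel_size_mm = voxel_size_mm),
            class = "parcellation")
}

## The default benchmark experiment at a given seed, memoised (shared by
## the ordering, recovery and consistency checks).
get_default_experiment <- function(seed) {
  memo(paste0("default_experiment_", seed), default_experiment(seed = seed))
}
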