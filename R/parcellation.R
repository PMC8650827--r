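## Synthetic parcellation: contiguous regions tiling the analysis
## hemisphere, grouped into spatially coherent sub-networks. A synthetic
## analogue of a whole-brain functional parcellation with its network
## assignment (e.g. 100 regions onto 17 networks); real atlas files can be
## supplied instead via read_parcellation().

#' Generate a synthetic parcellation
#'
#' Samples `n_regions` seed voxels in the analysis mask and assigns every
#' in-mask voxel to its nearest seed (Voronoi growth), then groups the
#' regions into `n_networks` sub-networks by k-means on the seed
#' coordinates, so networks are spatially coherent sets of regions.
#'
#' @param grid_shape integer length-3 voxel dimensions.
#' @param n_regions number of regions (>= n_networks).
#' @param n_networks number of sub-networks (>= 1).
#' @param seed integer RNG seed.
#' @param voxel_size_mm isotropic spacing in mm.
#' @param mask logical volume to tile; defaults to the left-hemisphere
#'   brain mask (the hemisphere lesions are collapsed onto).
#' @return an object of class `parcellation`: list with `label_grid`
#'   (integer 3-D array, 0 = background), `region_ids`,
#'   `region_to_network` (named integer vector), `network_ids`,
#'   `voxel_size_mm`.
#' @export
generate_parcellation <- function(grid_shape, n_regions = 100, n_networks = 17,
                                  seed = 1, voxel_size_mm = 4, mask = NULL) {
  stopifnot(n_regions >= n_networks, n_networks >= 1)
  grid_shape <- as.integer(grid_shape)
  if (is.null(mask)) mask <- make_hemisphere_mask(grid_shape)
  vox <- which(mask)
  if (n_regions > length(vox)) {
    stop(sprintf("n_regions (%d) exceeds available mask voxels (%d)",
                 n_regions, length(vox)))
  }
  with_seed(seed, {
    seeds <- sample_vec(vox, n_regions)
    sxyz <- index_to_ijk(seeds, grid_shape)
    vxyz <- index_to_ijk(vox, grid_shape)
    ## nearest-seed assignment, ties to the lower region id
    best <- rep(1L, length(vox))
    bestd <- rep(Inf, length(vox))
    for (r in seq_len(n_regions)) {
      d2 <- (vxyz[, 1] - sxyz[r, 1])^2 + (vxyz[, 2] - sxyz[r, 2])^2 +
        (vxyz[, 3] - sxyz[r, 3])^2
      upd <- d2 < bestd
      best[upd] <- r
      bestd[upd] <- d2[upd]
    }
    label_grid <- array(0L, dim = grid_shape)
    label_grid[vox] <- best
    if (n_networks == n_regions) {
      net <- seq_len(n_regions)
    } else if (n_networks == 1) {
      net <- rep(1L, n_regions)
    } else {
      km <- kmeans(sxyz, centers = n_networks, nstart = 10, iter.max = 100)
      net <- as.integer(km$cluster)
    }
    structure(list(label_grid = label_grid,
                   region_ids = seq_len(n_regions),
                   region_to_network = stats::setNames(net, seq_len(n_regions)),
                   network_ids = sort(unique(net)),
                   voxel_size_mm = voxel_size_mm),
              class = "parcellation")
  })
}

#' Read a parcellation from NIfTI + region-network CSV
#'
#' @param nifti_path integer-labelled NIfTI volume (0 = background).
#' @param map_path CSV with columns `region_id`, `network_id` (optional
#'   `name`).
#' @return a `parcellation`.
#' @export
read_parcellation <- function(nifti_path, map_path) {
  img <- RNifti::readNifti(nifti_path)
  if (length(dim(img)) != 3) stop("parcellation image must be 3-D")
  label_grid <- array(as.integer(round(img)), dim = dim(img))
  map <- read.csv(map_path)
  stopifnot(all(c("region_id", "network_id") %in% names(map)))
  present <- sort(unique(label_grid[label_grid > 0L]))
  missing <- setdiff(present, map$region_id)
  if (length(missing)) {
    stop("regions present in image but absent from map: ",
         paste(head(missing, 5), collapse = ", "))
  }
  structure(list(label_grid = label_grid,
                 region_ids = as.integer(map$region_id),
                 region_to_network = stats::setNames(as.integer(map$network_id),
                                                     map$region_id),
                 network_ids = sort(unique(as.integer(map$network_id))),
                 voxel_size_mm = RNifti::pixdim(img)[1]),
            class = "parcellation")
}

#' Write a parcellation to NIfTI + CSV
#' @param parc a `parcellation`.
#' @param nifti_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_parcellation <- function(parc, nifti_path, map_path) {
  write_image_nifti(parc$label_grid, parc$voxel_size_mm, nifti_path)
  write.csv(data.frame(region_id = as.integer(names(parc$region_to_network)),
                       network_id = as.integer(parc$region_to_network)),
            map_path, row.names = FALSE)
  invisible(c(nifti_path, map_path))
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions in %d networks over %d voxels\n",
              length(x$region_ids), length(x$network_ids),
              sum(x$label_grid > 0)))
  invisible(x)
}
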