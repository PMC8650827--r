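## Preprocessing: hemisphere collapse, Gaussian smoothing, vectorization of
## the cohort into the nonnegative matrix consumed by the representation
## learner. The brain's macroscopic vascular organisation is symmetric, so
## right-dominant lesions are mirrored onto the left hemisphere before any
## representation is learnt.

#' Collapse a lesion onto the canonical (left) hemisphere
#'
#' If strictly more lesion voxels lie right of the midsagittal plane the
#' whole grid is mirror-flipped about it; otherwise the mask is returned
#' unchanged (ties keep the original orientation). Idempotent.
#'
#' @param mask a `lesion_mask` (nonempty).
#' @return a `lesion_mask` with lesion mass left-of-or-on the midline at
#'   least that of the input.
#' @export
collapse_hemisphere <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (length(mask$voxels) == 0) stop("empty lesion")
  nx <- mask$grid_shape[1]
  i <- (mask$voxels - 1L) %% nx + 1L
  mid <- (nx + 1) / 2                     # fractional for even extents
  n_left <- sum(i < mid)
  n_right <- sum(i > mid)
  if (n_right > n_left) {
    mask$voxels <- sort(mirror_indices(mask$voxels, mask$grid_shape))
  }
  mask
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Smooths with a separable Gaussian of the given full width at half
#' maximum, `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in mm converted to
#' voxels by the spacing. The discrete kernel is normalised to unit sum, so
#' total mass is conserved for interior-supported inputs; boundaries are
#' zero-padded. `fwhm_mm = 0` is the identity.
#'
#' @param vol numeric 3-D array.
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @return numeric 3-D array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = 1) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol + 0)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  rad <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- exp(-(seq(-rad, rad))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  out <- vol + 0   # force double
  d <- dim(vol)
  for (ax in 1:3) {
    acc <- array(0, d)
    for (kk in seq(-rad, rad)) {
      wk <- w[kk + rad + 1]
      if (kk == 0) { acc <- acc + wk * out; next }
      src <- seq_len(d[ax] - abs(kk))
      if (kk > 0) { dst <- src + kk } else { dst <- src; src <- src + abs(kk) }
      if (ax == 1) acc[dst, , ] <- acc[dst, , ] + wk * out[src, , ]
      else if (ax == 2) acc[, dst, ] <- acc[, dst, ] + wk * out[, src, ]
      else acc[, , dst] <- acc[, , dst] + wk * out[, , src]
    }
    out <- acc
  }
  out
}

#' Lesion volume in cubic millimetres
#' @param mask a `lesion_mask`.
#' @return numeric, nonzero-voxel count times voxel volume.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  length(mask$voxels) * mask$voxel_size_mm^3
}

#' Build the cohort data matrix
#'
#' Per subject: collapse onto the canonical hemisphere, smooth, extract
#' in-mask voxels as one row. The result is the n x V nonnegative matrix
#' all representations are learnt from. The analysis mask defaults to the
#' collapsed-hemisphere brain mask; pass
#' `mask = array(TRUE, grid_shape)` to vectorise the entire grid.
#'
#' @param cohort a `lesion_cohort` (or list of `lesion_mask` sharing a grid).
#' @param fwhm_mm Gaussian smoothing FWHM in mm (default 2).
#' @param mask logical volume selecting the V analysis voxels; default the
#'   left-hemisphere brain mask.
#' @return an object of class `data_matrix`: list with `values` (n x V),
#'   `voxel_index` (linear indices of the columns), `fwhm_mm`, `mask`,
#'   `grid_shape`, `voxel_size_mm`, `subject_ids`.
#' @export
build_data_matrix <- function(cohort, fwhm_mm = 2, mask = NULL) {
  masks <- if (inherits(cohort, "lesion_cohort")) cohort$masks else cohort
  stopifnot(length(masks) >= 1)
  gs <- masks[[1]]$grid_shape
  vs <- masks[[1]]$voxel_size_mm
  if (is.null(mask)) mask <- make_hemisphere_mask(gs)
  if (sum(mask) == 0) stop("analysis mask is empty")
  cols <- which(mask)
  X <- matrix(0, nrow = length(masks), ncol = length(cols))
  ids <- character(length(masks))
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    if (!identical(m$grid_shape, gs)) {
      stop(sprintf("grid shape mismatch for subject %s", m$subject_id))
    }
    m <- collapse_hemisphere(m)
    vol <- indices_to_volume(m$voxels, gs) + 0
    if (fwhm_mm > 0) vol <- smooth_volume(vol, fwhm_mm, m$voxel_size_mm)
    X[s, ] <- vol[cols]
    ids[s] <- m$subject_id
  }
  structure(list(values = X, voxel_index = cols, fwhm_mm = fwhm_mm,
                 mask = mask, grid_shape = gs, voxel_size_mm = vs,
                 subject_ids = ids),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d subjects x %d voxels (fwhm %g mm)\n",
              nrow(x$values), ncol(x$values), x$fwhm_mm))
  invisible(x)
}
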