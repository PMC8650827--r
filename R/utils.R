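## Internal helpers shared across modules: seed derivation, grid geometry,
## sparse <-> dense mask conversion, morphology primitives.

#' Derive a stage seed from a master seed
#'
#' All randomness in the pipeline flows through integer seeds derived
#' deterministically from one master seed, so that a single integer
#' reproduces a full run. The derivation is a fixed affine map modulo a
#' prime below 2^31.
#'
#' @param master integer master seed.
#' @param offset integer stage/step offset (>= 0).
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), is.numeric(offset))
  as.integer((abs(as.numeric(master)) * 48271 + as.numeric(offset) * 16807 + 1) %% 2147483587)
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Ellipsoidal brain mask for a voxel grid
#'
#' A smooth convex stand-in for a brain mask: the ellipsoid inscribed in the
#' grid. The first array axis is the left-right axis with the midsagittal
#' plane at its centre.
#'
#' @param grid_shape integer length-3 vector of voxel dimensions.
#' @return logical 3-D array.
#' @export
make_brain_mask <- function(grid_shape) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2))
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  semi <- d / 2 - 0.5
  ax <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  ay <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  az <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  arr <- outer(outer(ax, ay, `+`), az, `+`) <= 1
  dim(arr) <- d
  arr
}

#' Left-hemisphere analysis mask
#'
#' The half of [make_brain_mask()] left of the midsagittal plane (first-axis
#' index below the midline; for odd extents the middle plane is excluded).
#'
#' @inheritParams make_brain_mask
#' @return logical 3-D array.
#' @export
make_hemisphere_mask <- function(grid_shape) {
  m <- make_brain_mask(grid_shape)
  nx <- dim(m)[1]
  keep <- seq_len(nx) <= nx %/% 2
  m[!keep, , ] <- FALSE
  m
}

## Mirror a 3-D array about the midsagittal plane (reverse the first axis).
mirror_volume <- function(arr) {
  arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
}

## Mirror linear voxel indices about the midsagittal plane.
mirror_indices <- function(idx, grid_shape) {
  nx <- grid_shape[1]
  i0 <- (idx - 1L) %% nx                # 0-based x coordinate
  idx - i0 + (nx - 1L - i0)
}

## Linear index -> integer (i,j,k) matrix (1-based).
index_to_ijk <- function(idx, grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  z <- (idx - 1L) %/% (nx * ny)
  r <- (idx - 1L) %% (nx * ny)
  cbind(i = r %% nx + 1L, j = r %/% nx + 1L, k = z + 1L)
}

## Dense logical volume from sorted linear indices.
indices_to_volume <- function(idx, grid_shape) {
  v <- array(FALSE, dim = grid_shape)
  v[idx] <- TRUE
  v
}

## 6-neighbour binary dilation/erosion on linear indices, clipped to `within`
## (a logical volume) for dilation.
dilate_indices <- function(idx, grid_shape, within = NULL) {
  if (length(idx) == 0) return(integer(0))
  ijk <- index_to_ijk(idx, grid_shape)
  out <- idx
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1L & nb[, ax] <= grid_shape[ax]
      nb <- nb[ok, , drop = FALSE]
      out <- c(out, (nb[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
                 (nb[, 2] - 1L) * grid_shape[1] + nb[, 1])
    }
  }
  out <- sort(unique(out))
  if (!is.null(within)) out <- out[within[out]]
  out
}

erode_indices <- function(idx, grid_shape) {
  if (length(idx) == 0) return(integer(0))
  v <- indices_to_volume(idx, grid_shape)
  keep <- rep(TRUE, length(idx))
  ijk <- index_to_ijk(idx, grid_shape)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[, ax] <- nb[, ax] + s
      inside <- nb[, ax] >= 1L & nb[, ax] <= grid_shape[ax]
      lin <- (nb[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
        (nb[, 2] - 1L) * grid_shape[1] + nb[, 1]
      has <- inside
      has[inside] <- v[lin[inside]]
      keep <- keep & has
    }
  }
  idx[keep]
}

## sample() without the length-1 surprise.
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Dice similarity of two voxel sets
#'
#' `2|A∩B| / (|A|+|B|)`, the standard overlap score for binary masks.
#' Defined as 0 when both sets are empty.
#'
#' @param a,b integer vectors of linear voxel indices (or logical volumes).
#' @return numeric in \[0, 1\].
#' @export
dice_similarity <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  tot <- length(a) + length(b)
  if (tot == 0) return(0)
  2 * length(intersect(a, b)) / tot
}
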