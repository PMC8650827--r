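## NIfTI input/output for lesion masks, parcellations and archetype
## images, plus cohort-level readers/writers with a CSV manifest.

#' Read a binary lesion mask from NIfTI
#'
#' Values are binarised at 0.5; spacing is taken from the header.
#'
#' @param path NIfTI file (3-D).
#' @param subject_id,age optional metadata to attach.
#' @return a `lesion_mask`.
#' @export
read_lesion_nifti <- function(path, subject_id = NA_character_, age = NA_real_) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop(sprintf("expected a 3-D image, got %d-D", length(d)))
  vox <- which(img >= 0.5)
  lesion_mask(vox, d, RNifti::pixdim(img)[1],
              subject_id = subject_id, age = age)
}

#' Write a 3-D volume as NIfTI
#'
#' @param grid numeric/logical/integer 3-D array.
#' @param voxel_size_mm isotropic spacing written to the header.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, the path.
#' @export
write_image_nifti <- function(grid, voxel_size_mm, path) {
  stopifnot(length(dim(grid)) == 3)
  img <- RNifti::asNifti(grid + 0)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort as per-subject NIfTI masks plus a CSV manifest
#'
#' @param cohort a `lesion_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(cohort$masks))
  for (s in seq_along(cohort$masks)) {
    m <- cohort$masks[[s]]
    files[s] <- file.path(dir, paste0(m$subject_id, "_mask.nii.gz"))
    write_image_nifti(as_volume(m), m$voxel_size_mm, files[s])
  }
  manifest <- cbind(cohort$manifest, file = basename(files))
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort from a manifest CSV and its NIfTI masks
#'
#' @param manifest_path CSV with columns subject_id, age, file (and
#'   optionally planted_node), files relative to its directory.
#' @return a `lesion_cohort` (without simulator tree/spec).
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "age", "file") %in% names(manifest)))
  dir <- dirname(manifest_path)
  masks <- lapply(seq_len(nrow(manifest)), function(s) {
    m <- read_lesion_nifti(file.path(dir, manifest$file[s]),
                           subject_id = manifest$subject_id[s],
                           age = manifest$age[s])
    if ("planted_node" %in% names(manifest)) {
      m$planted_node <- as.integer(manifest$planted_node[s])
    }
    m
  })
  gs <- masks[[1]]$grid_shape
  for (m in masks) {
    if (!identical(m$grid_shape, gs)) {
      stop("grid shape mismatch for subject ", m$subject_id)
    }
  }
  keep <- intersect(c("subject_id", "age", "planted_node"), names(manifest))
  structure(list(masks = masks, manifest = manifest[, keep],
                 grid_shape = gs, voxel_size_mm = masks[[1]]$voxel_size_mm,
                 tree = NULL, spec = NULL),
            class = "lesion_cohort")
}

#' Write archetype centroid images
#' @param cluster_model a `cluster_model`.
#' @param dir output directory; files `archetype_<id>.nii.gz`.
#' @param voxel_size_mm spacing for the headers.
#' @return invisibly, the file paths.
#' @export
write_archetypes <- function(cluster_model, dir, voxel_size_mm) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cluster_model$centroids, function(ct) {
    p <- file.path(dir, sprintf("archetype_%02d.nii.gz", ct$cluster_id))
    write_image_nifti(ct$grid, voxel_size_mm, p)
    p
  }, character(1))
  invisible(paths)
}
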