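## Synthetic lesion-deficit ground truth by the regional damage rule: a
## functional sub-network is "affected" when at least `threshold` (default
## 15%) of the voxels of at least one of its constituent regions are
## lesioned. Damage is never aggregated across regions; the rule is a
## per-region OR. White-matter tracts are handled as ordinary regions
## assigned to their network.

#' Fraction of a parcellation region damaged by a lesion
#'
#' Lesions are collapsed onto the canonical hemisphere (the hemisphere the
#' parcellation is defined on) before overlap.
#'
#' @param mask a `lesion_mask`.
#' @param parcellation a `parcellation`.
#' @param region_id region label present in the parcellation.
#' @return `|lesion ∩ region| / |region|` in \[0, 1\].
#' @export
damage_fraction <- function(mask, parcellation, region_id) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (!region_id %in% parcellation$region_ids) {
    stop("unknown region_id: ", region_id)
  }
  region <- which(parcellation$label_grid == region_id)
  if (length(region) == 0) stop("region ", region_id, " is empty")
  if (length(mask$voxels) == 0) return(0)
  m <- collapse_hemisphere(mask)
  length(intersect(m$voxels, region)) / length(region)
}

#' Label sub-network deficits for a cohort
#'
#' A network is affected iff the maximum damage fraction over its regions
#' is at least `threshold` (boundary inclusive).
#'
#' @param cohort a `lesion_cohort` (or list of `lesion_mask`).
#' @param parcellation a `parcellation` on the same grid.
#' @param threshold damage fraction in (0, 1\] (default 0.15).
#' @return an object of class `deficit_table`: list with `values`
#'   (n_subjects x n_networks logical matrix, columns named by network id),
#'   `region_fractions` (n_subjects x n_regions), `threshold`.
#' @export
label_deficits <- function(cohort, parcellation, threshold = 0.15) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  masks <- if (inherits(cohort, "lesion_cohort")) cohort$masks else cohort
  rids <- parcellation$region_ids
  net_of <- parcellation$region_to_network[as.character(rids)]
  nets <- parcellation$network_ids
  if (!all(nets %in% net_of)) stop("network with no regions")
  region_sizes <- vapply(rids, function(r) sum(parcellation$label_grid == r),
                         numeric(1))
  if (any(region_sizes == 0)) stop("parcellation contains an empty region")
  lab <- parcellation$label_grid
  frac <- matrix(0, length(masks), length(rids),
                 dimnames = list(NULL, rids))
  for (s in seq_along(masks)) {
    if (length(masks[[s]]$voxels) == 0) next   # empty lesion: no damage
    m <- collapse_hemisphere(masks[[s]])
    hit <- lab[m$voxels]
    hit <- hit[hit > 0L]
    if (length(hit)) {
      tab <- tabulate(hit, nbins = max(rids))
      frac[s, ] <- tab[rids] / region_sizes
    }
  }
  vals <- vapply(nets, function(nw) {
    cols <- which(net_of == nw)
    apply(frac[, cols, drop = FALSE], 1, max) >= threshold
  }, logical(length(masks)))
  if (length(masks) == 1) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- nets
  structure(list(values = vals, region_fractions = frac,
                 threshold = threshold),
            class = "deficit_table")
}

#' Write / read a deficit table as CSV
#' @param deficits a `deficit_table`.
#' @param path CSV path; columns `subject_id` then one 0/1 column per
#'   network (`net_<id>`).
#' @param subject_ids optional subject identifiers.
#' @return invisibly, the path.
#' @export
write_deficits <- function(deficits, path, subject_ids = NULL) {
  v <- deficits$values
  df <- data.frame(subject_id = subject_ids %||% seq_len(nrow(v)))
  for (j in seq_len(ncol(v))) df[[paste0("net_", colnames(v)[j])]] <- as.integer(v[, j])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
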