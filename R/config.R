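## Run configuration: a flat named list whose defaults are the pipeline's
## canonical settings (2 mm FWHM smoothing, rank-50 NMF, perplexity-30
## t-SNE, structure-aware filtering mu = 0.2 / r = 0.1, Ward 30 clusters
## amalgamated to 21, 15% damage threshold, 100 regions / 17 networks,
## 10 balanced repeats with 5 inner folds).

config_defaults <- function() {
  list(
    ## simulator
    n_subjects = 400L, grid_shape = c(48L, 56L, 48L), voxel_size_mm = 4,
    tree_depth = 3L, noise_rate = 0.03, volume_jitter = 0.15,
    age_mean = 63.89, age_sd = 15.91, age_bounds = c(18, 97),
    right_hemisphere_prob = 0.5,
    ## preprocessing
    fwhm_mm = 2.0,
    ## representation
    k = 50L, perplexity = 30, mu = 0.2, r = 0.1,
    n_initial = 30L, n_final = 21L,
    nmf_max_iter = 500L, nmf_tol = 1e-5, tsne_iter = 1000L,
    ## ground truth
    threshold = 0.15, n_regions = 100L, n_networks = 17L,
    ## prediction
    kinds = c("baseline", "categorial", "2d", "50d"),
    n_outer = 10L, inner_folds = 5L, learning_rate = 0.1,
    ## run control
    seed = 1L, out_dir = "lesionlatent_run"
  )
}

config_ranges <- function() {
  list(threshold = c(1e-12, 1), fwhm_mm = c(0, Inf), mu = c(0, 1),
       r = c(1e-12, Inf), perplexity = c(1, Inf), k = c(1, Inf),
       noise_rate = c(0, 1), volume_jitter = c(0, 1 - 1e-12),
       right_hemisphere_prob = c(0, 1), n_subjects = c(1, Inf),
       tree_depth = c(1, Inf), n_regions = c(1, Inf),
       n_networks = c(1, Inf), n_initial = c(1, Inf), n_final = c(1, Inf),
       n_outer = c(1, Inf), inner_folds = c(2, Inf),
       learning_rate = c(1e-6, 1))
}

#' Load a run configuration
#'
#' Reads a flat YAML file of `key: value` settings, fills unset keys with
#' the defaults, rejects unknown keys (with a nearest-key suggestion) and
#' out-of-range values.
#'
#' @param path YAML file, or NULL/absent file for pure defaults.
#' @return named list of resolved settings.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        near <- vapply(unknown, function(k) {
          hit <- agrep(k, names(cfg), max.distance = 0.3, value = TRUE)
          if (length(hit)) sprintf(" (did you mean '%s'?)", hit[1]) else ""
        }, character(1))
        stop("unknown config key(s): ",
             paste0("'", unknown, "'", near, collapse = ", "))
      }
      for (k in names(user)) cfg[[k]] <- user[[k]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  rng <- config_ranges()
  for (k in names(rng)) {
    v <- cfg[[k]]
    if (!is.numeric(v) || any(v < rng[[k]][1]) || any(v > rng[[k]][2])) {
      stop(sprintf("config key '%s' out of range [%g, %g]: %s",
                   k, rng[[k]][1], rng[[k]][2],
                   paste(format(v), collapse = ", ")))
    }
  }
  bad_kind <- setdiff(cfg$kinds, c("baseline", "categorial", "2d", "50d"))
  if (length(bad_kind)) stop("unknown representation kind: ",
                             paste(bad_kind, collapse = ", "))
  if (cfg$n_final > cfg$n_initial) stop("config key 'n_final' exceeds 'n_initial'")
  if (length(cfg$age_bounds) != 2 || cfg$age_bounds[1] > cfg$age_bounds[2]) {
    stop("config key 'age_bounds' must be an ordered pair")
  }
  invisible(cfg)
}
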