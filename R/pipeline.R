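## End-to-end drivers: representation learning from a data matrix, the
## default benchmark experiment, and the fully seeded run_all() pipeline
## that writes every artefact to disk.

#' Learn all lesion representations from a data matrix
#'
#' NMF scores -> t-SNE -> structure-aware filtering -> Ward clustering ->
#' centroid archetypes -> amalgamation. Stage seeds are derived from
#' `seed`.
#'
#' @param dm a `data_matrix`.
#' @param cohort the `lesion_cohort` behind `dm` (for centroid images).
#' @param k NMF rank.
#' @param perplexity,tsne_iter t-SNE settings.
#' @param mu,r structure-aware filtering settings.
#' @param n_initial Ward cluster count.
#' @param n_final final cluster count after amalgamation (`= n_initial`
#'   for no merging); ignored when `merge_map` is given.
#' @param merge_map optional explicit merge map (see [amalgamate()]).
#' @param seed master seed for this stage.
#' @param nmf_max_iter,nmf_tol NMF stopping controls.
#' @return list with `nmf` (`nmf_model`), `embedding` (filtered
#'   `embedding_2d`), `embedding_raw`, `initial_labels`, `cluster_model`.
#' @export
fit_representation <- function(dm, cohort, k = 50, perplexity = 30,
                               mu = 0.2, r = 0.1, n_initial = 30,
                               n_final = 21, merge_map = NULL, seed = 1,
                               nmf_max_iter = 500, nmf_tol = 1e-5,
                               tsne_iter = 1000) {
  nmf <- fit_nmf(dm, k = k, seed = derive_seed(seed, 31),
                 max_iter = nmf_max_iter, tol = nmf_tol)
  emb_raw <- embed_2d(nmf$scores, perplexity = perplexity,
                      seed = derive_seed(seed, 32), n_iter = tsne_iter,
                      filter_mu = mu, filter_r = r)
  emb <- saf_filter(emb_raw, mu = mu, r = r)
  labels <- ward_cluster(emb, n_initial)
  cents <- compute_centroids(cohort, labels)
  cm <- if (!is.null(merge_map)) {
    amalgamate(labels, cents, merge_map = merge_map)
  } else if (n_final < n_initial) {
    amalgamate(labels, cents, target_n = n_final)
  } else {
    amalgamate(labels, cents, merge_map = seq_len(n_initial))
  }
  list(nmf = nmf, embedding = emb, embedding_raw = emb_raw,
       initial_labels = labels, cluster_model = cm)
}

#' Run the default synthetic benchmark experiment
#'
#' The package's canonical study conditions: a 400-subject cohort on the
#' desk-scale grid from a depth-3 vascular tree sampled at its 8 leaves
#' (noise 3%, volume jitter 15%), a 40-region / 6-network parcellation,
#' 8 Ward archetypes (matching the planted leaf count, no amalgamation),
#' the 15% damage rule, and 10 balanced repeats of the four-representation
#' benchmark.
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param n_regions,n_networks parcellation size.
#' @param n_clusters Ward cluster count.
#' @param n_outer balanced resampling repeats.
#' @param kinds representation kinds to benchmark.
#' @param nmf_max_iter,nmf_tol NMF stopping controls (trimmed relative to
#'   the full-scale defaults; see the methods vignette).
#' @param permute_labels no-signal null switch (see [run_experiment()]).
#' @return list with `cohort`, `dm`, `rep` (from [fit_representation()]),
#'   `parcellation`, `deficits`, `features`, `results`.
#' @export
default_experiment <- function(seed = 11, n_subjects = 400, n_regions = 40,
                               n_networks = 6, n_clusters = 8, n_outer = 10,
                               kinds = c("baseline", "categorial", "2d", "50d"),
                               nmf_max_iter = 200, nmf_tol = 1e-4,
                               permute_labels = FALSE) {
  spec <- cohort_spec(n_subjects = n_subjects, seed = derive_seed(seed, 10))
  cohort <- generate_cohort(spec)
  dm <- build_data_matrix(cohort, fwhm_mm = 2)
  rep <- fit_representation(dm, cohort, k = 50, n_initial = n_clusters,
                            n_final = n_clusters, seed = derive_seed(seed, 30),
                            nmf_max_iter = nmf_max_iter, nmf_tol = nmf_tol)
  parc <- generate_parcellation(spec$grid_shape, n_regions, n_networks,
                                seed = derive_seed(seed, 20),
                                voxel_size_mm = spec$voxel_size_mm)
  deficits <- label_deficits(cohort, parc, threshold = 0.15)
  feats <- representation_features(cohort, rep$cluster_model, rep$embedding,
                                   rep$nmf, kinds = kinds)
  results <- run_experiment(feats, deficits, n_outer = n_outer,
                            seed = derive_seed(seed, 50),
                            permute_labels = permute_labels)
  list(cohort = cohort, dm = dm, rep = rep, parcellation = parc,
       deficits = deficits, features = feats, results = results)
}

#' Run the full pipeline and write every artefact
#'
#' simulate -> preprocess -> embed -> cluster -> label-deficits ->
#' predict -> report, with every stage seed derived from `config$seed`.
#' Two runs with the same config produce byte-identical result CSVs.
#'
#' @param config named list from [load_config()] (defaults if NULL).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, the output directory.
#' @export
run_all <- function(config = NULL, out_dir = NULL) {
  cfg <- config %||% load_config()
  validate_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  master <- cfg$seed
  t0 <- Sys.time()
  log_msg <- function(fmt, ...) message(sprintf(paste0("[run_all] ", fmt), ...))
  log_msg("config: %s", jsonlite::toJSON(cfg, auto_unbox = TRUE))

  spec <- cohort_spec(n_subjects = cfg$n_subjects, grid_shape = cfg$grid_shape,
                      voxel_size_mm = cfg$voxel_size_mm,
                      tree_depth = cfg$tree_depth, noise_rate = cfg$noise_rate,
                      volume_jitter = cfg$volume_jitter, age_mean = cfg$age_mean,
                      age_sd = cfg$age_sd, age_bounds = cfg$age_bounds,
                      right_hemisphere_prob = cfg$right_hemisphere_prob,
                      seed = derive_seed(master, 10))
  cohort <- generate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  log_msg("simulated %d subjects", cfg$n_subjects)

  parc <- generate_parcellation(cfg$grid_shape, cfg$n_regions, cfg$n_networks,
                                seed = derive_seed(master, 20),
                                voxel_size_mm = cfg$voxel_size_mm)
  write_parcellation(parc, file.path(out_dir, "parcellation.nii.gz"),
                     file.path(out_dir, "region_network_map.csv"))

  dm <- build_data_matrix(cohort, fwhm_mm = cfg$fwhm_mm)
  log_msg("data matrix %d x %d", nrow(dm$values), ncol(dm$values))

  rep <- fit_representation(dm, cohort, k = cfg$k, perplexity = cfg$perplexity,
                            mu = cfg$mu, r = cfg$r, n_initial = cfg$n_initial,
                            n_final = cfg$n_final, seed = derive_seed(master, 30),
                            nmf_max_iter = cfg$nmf_max_iter,
                            nmf_tol = cfg$nmf_tol, tsne_iter = cfg$tsne_iter)
  write.csv(data.frame(subject_id = cohort$manifest$subject_id,
                       rep$nmf$scores), file.path(out_dir, "nmf_scores.csv"),
            row.names = FALSE)
  write.csv(data.frame(subject_id = cohort$manifest$subject_id,
                       x = rep$embedding$coords[, 1],
                       y = rep$embedding$coords[, 2],
                       cluster = rep$cluster_model$labels),
            file.path(out_dir, "coords.csv"), row.names = FALSE)
  write_archetypes(rep$cluster_model, file.path(out_dir, "archetypes"),
                   cfg$voxel_size_mm)
  log_msg("representation: %d -> %d clusters", cfg$n_initial,
          rep$cluster_model$n_final)

  deficits <- label_deficits(cohort, parc, threshold = cfg$threshold)
  write_deficits(deficits, file.path(out_dir, "deficits.csv"),
                 subject_ids = cohort$manifest$subject_id)

  feats <- representation_features(cohort, rep$cluster_model, rep$embedding,
                                   rep$nmf, kinds = cfg$kinds)
  results <- run_experiment(feats, deficits, n_outer = cfg$n_outer,
                            seed = derive_seed(master, 50),
                            grid = gbm_grid(inner_folds = cfg$inner_folds))
  write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)

  summ <- summarize_results(results)
  anova <- anova_two_way(results, "accuracy")
  export_report(summ, anova, out_dir,
                manifest = list(config = cfg, master_seed = master,
                                stage_seeds = list(
                                  cohort = derive_seed(master, 10),
                                  parcellation = derive_seed(master, 20),
                                  representation = derive_seed(master, 30),
                                  experiment = derive_seed(master, 50)),
                                n_subjects = nrow(cohort$manifest),
                                elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                                  units = "secs"))))
  log_msg("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out_dir)
}
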