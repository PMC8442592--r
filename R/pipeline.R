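#' Configuration for a full synthetic study
#'
#' Bundles every stage parameter with defaults matching the pipeline's
#' reference settings: 10 s initial drop, 0.008-0.1 Hz band, 0.5 mm FD
#' scrubbing threshold, 10-fold outer / 5-fold inner cross-validation,
#' 5000 permutations, edge alpha 0.05 Bonferroni-divided by E, enrichment
#' alpha 0.025 divided by 45. All randomness flows from `seed`.
#'
#' @param n_discovery,n_validation Cohort sizes.
#' @param n_rois,n_timepoints,tr_seconds,ls_mean,ls_sd,n_signal_edges,effect_size,edge_noise_sd,motion_spike_rate,family_pairs
#'   Generator settings (see [cohort_spec()]).
#' @param mode `"timeseries"` runs the full post-processing path;
#'   `"edge"` generates Fisher-z features directly.
#' @param drop_seconds,band,fd_threshold_mm,min_frames Post-processing
#'   settings (see [preprocess_subject()]).
#' @param n_components,k,inner_k,lambda_grid Model settings (see
#'   [fit_ls_pipeline()]).
#' @param n_perm Permutation iterations per stage.
#' @param alpha_edges,alpha_enrichment Significance levels (see
#'   [contribution_analysis()]).
#' @param seed Master seed.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(n_discovery = 100, n_validation = 300, n_rois = 40,
                       n_timepoints = 300, tr_seconds = 0.72,
                       ls_mean = 54.47, ls_sd = 9.0, n_signal_edges = 30,
                       effect_size = 0.5, edge_noise_sd = 1,
                       motion_spike_rate = 0, family_pairs = 0,
                       mode = c("edge", "timeseries"), drop_seconds = 10,
                       band = c(0.008, 0.1), fd_threshold_mm = 0.5,
                       min_frames = 50, n_components = "max", k = 10,
                       inner_k = 5, lambda_grid = default_lambda_grid(),
                       n_perm = 5000, alpha_edges = 0.05,
                       alpha_enrichment = 0.025, seed = 1) {
  cfg <- list(n_discovery = n_discovery, n_validation = n_validation,
              n_rois = n_rois, n_timepoints = n_timepoints,
              tr_seconds = tr_seconds, ls_mean = ls_mean, ls_sd = ls_sd,
              n_signal_edges = n_signal_edges, effect_size = effect_size,
              edge_noise_sd = edge_noise_sd,
              motion_spike_rate = motion_spike_rate,
              family_pairs = family_pairs, mode = match.arg(mode),
              drop_seconds = drop_seconds, band = band,
              fd_threshold_mm = fd_threshold_mm, min_frames = min_frames,
              n_components = n_components, k = k, inner_k = inner_k,
              lambda_grid = lambda_grid, n_perm = n_perm,
              alpha_edges = alpha_edges,
              alpha_enrichment = alpha_enrichment, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

# One population is generated (n_discovery + n_validation subjects) and
# split, mirroring the design in which discovery and validation cohorts are
# disjoint subsets of a single study sample sharing the same trait-coupled
# edge structure.
cohort_features <- function(cfg, seed) {
  spec <- cohort_spec(
    n_subjects = cfg$n_discovery + cfg$n_validation, n_rois = cfg$n_rois,
    n_timepoints = cfg$n_timepoints, tr_seconds = cfg$tr_seconds,
    ls_mean = cfg$ls_mean, ls_sd = cfg$ls_sd,
    n_signal_edges = cfg$n_signal_edges, effect_size = cfg$effect_size,
    edge_noise_sd = cfg$edge_noise_sd,
    motion_spike_rate = cfg$motion_spike_rate,
    family_pairs = cfg$family_pairs, seed = seed)
  if (cfg$mode == "edge") {
    coh <- generate_edge_cohort(spec)
    features <- coh$features
    ls <- coh$ls
    exclusions <- NULL
    signal_edges <- coh$signal_edges
    edge_index <- coh$edge_index
  } else {
    coh <- generate_timeseries_cohort(spec)
    fm <- assemble_features(coh$subjects, drop_seconds = cfg$drop_seconds,
                            band = cfg$band,
                            fd_threshold_mm = cfg$fd_threshold_mm,
                            min_frames = cfg$min_frames)
    kept <- !fm$subjects$excluded
    features <- fm$features
    ls <- coh$ls[kept, ]
    exclusions <- fm$subjects
    signal_edges <- coh$signal_edges
    edge_index <- fm$edge_index
  }
  n_d <- min(cfg$n_discovery, nrow(features))
  d_idx <- seq_len(n_d)
  v_idx <- setdiff(seq_len(nrow(features)), d_idx)
  list(
    discovery = list(features = features[d_idx, , drop = FALSE],
                     y = ls$ls_score[d_idx], ls = ls[d_idx, ]),
    validation = list(features = features[v_idx, , drop = FALSE],
                      y = ls$ls_score[v_idx], ls = ls[v_idx, ]),
    signal_edges = signal_edges, edge_index = edge_index,
    exclusions = exclusions)
}

#' Run the whole study end to end on synthetic cohorts
#'
#' Generates discovery and validation cohorts, post-processes them (in
#' time-series mode), fits the PCA + cross-validated ridge pipeline on the
#' discovery cohort, runs the discovery permutation test, applies the
#' averaged fold models to the validation cohort with its own permutation
#' test, and performs the edge-contribution and network-enrichment
#' analyses. Every stage seed is derived from the master seed, so two runs
#' with the same configuration produce identical results (and identical
#' bytes on disk when `out_dir` is given).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, predictions,
#'   contribution and enrichment tables (TSV), permutation summaries
#'   (JSON) and a manifest with the configuration, derived seeds and MD5
#'   hashes of every written file are stored there.
#' @return List with `pipeline`, `r_discovery`, `perm_discovery`,
#'   `r_validation`, `perm_validation`, `contribution`, `enrichment`,
#'   `atlas`, `truth` (planted edges per cohort), `config`.
#' @export
run_ls_study <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 4)
  pop <- cohort_features(config, seeds[1])
  disc <- pop$discovery
  val <- pop$validation

  pipeline <- fit_ls_pipeline(disc$features, disc$y,
                              n_components = config$n_components,
                              k = config$k, inner_k = config$inner_k,
                              lambda_grid = config$lambda_grid,
                              seed = seeds[3])
  perm_disc <- permute_discovery(pipeline$scores, disc$y, k = config$k,
                                 inner_k = config$inner_k,
                                 lambda_grid = config$lambda_grid,
                                 n_perm = config$n_perm, seed = seeds[3])
  scores_val <- project_pca(pipeline$pca, val$features)
  pred_val <- predict_external(pipeline$cv, scores_val)
  r_val <- evaluate_predictions(pred_val, val$y)$r
  perm_val <- permute_validation(pipeline$scores, disc$y, scores_val,
                                 val$y, k = config$k,
                                 inner_k = config$inner_k,
                                 lambda_grid = config$lambda_grid,
                                 n_perm = config$n_perm, seed = seeds[4])
  atlas <- default_atlas(config$n_rois)
  contrib <- contribution_analysis(pipeline, atlas, pop$edge_index,
                                   alpha_edges = config$alpha_edges,
                                   alpha_enrichment = config$alpha_enrichment)

  result <- list(
    pipeline = pipeline, r_discovery = pipeline$r_discovery,
    perm_discovery = perm_disc, r_validation = r_val,
    perm_validation = perm_val,
    predictions_discovery = dplyr::mutate(pipeline$oof,
                                          subject_id = disc$ls$subject_id,
                                          actual = disc$y),
    predictions_validation = tibble::tibble(
      subject_id = val$ls$subject_id, actual = val$y, predicted = pred_val),
    contribution = contrib$contributions, enrichment = contrib$enrichment,
    atlas = atlas,
    truth = list(signal_edges = pop$signal_edges,
                 exclusions = pop$exclusions),
    seeds = seeds, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(result$predictions_discovery,
                     file.path(out_dir, "predictions_discovery.tsv"))
    readr::write_tsv(result$predictions_validation,
                     file.path(out_dir, "predictions_validation.tsv"))
    readr::write_tsv(result$contribution,
                     file.path(out_dir, "edge_contributions.tsv"))
    readr::write_tsv(result$enrichment,
                     file.path(out_dir, "network_enrichment.tsv"))
    for (stage in c("discovery", "validation")) {
      pr <- if (stage == "discovery") perm_disc else perm_val
      jsonlite::write_json(
        list(stage = stage, observed_r = pr$observed_r,
             p_value = pr$p_value, n_perm = pr$n_perm, seed = pr$seed),
        file.path(out_dir, paste0("permutation_", stage, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    manifest <- list(
      config = unclass(config), seeds = seeds,
      hashes = as.list(tools::md5sum(file.path(out_dir, files))))
    names(manifest$hashes) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
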