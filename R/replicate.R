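#' Configuration for an end-to-end replication run
#'
#' Gathers every tunable of the pipeline in one place; all values are
#' echoed verbatim into the run's provenance record. The defaults define
#' the desk-scale study profile: a 16^3 grid at 2 mm, 6 bundles, 10
#' normative subjects, 64 network-training lesions and 60 patients.
#'
#' @param grid_size cube edge of the common grid (divisible by 8).
#' @param voxel_size mm per voxel.
#' @param margin brain-mask margin (voxels).
#' @param n_bundles,per_bundle,jitter_sd,n_subjects phantom tractogram
#'   parameters.
#' @param n_train_pairs lesions/disconnectomes used to train the network.
#' @param lesion_radius length-2 semi-axis range (voxels).
#' @param base_filters,epochs,batch_size,learning_rate,weight_decay,patience
#'   network profile (width scales from `base_filters`; the full-scale
#'   profile is 16).
#' @param n_patients,patient_split_fraction clinical-cohort emulation.
#' @param n_tests,noise_sd planted score battery.
#' @param n_neighbors,min_dist,raster_resolution,sigma morphospace
#'   parameters.
#' @param binarize_threshold,corr_threshold,top_k,n_components analysis
#'   thresholds (defaults 1e-4, 0.2, 3, 3).
#' @param seed global integer seed; every stage derives its own seed from it.
#' @param out_dir optional output directory (artifacts + report JSON).
#' @return A `run_config` object.
#' @export
run_config <- function(grid_size = 16, voxel_size = 2, margin = 1,
                       n_bundles = 6, per_bundle = 16, jitter_sd = 0.75,
                       n_subjects = 10, n_train_pairs = 64,
                       lesion_radius = c(2, 5),
                       base_filters = 4, epochs = 12, batch_size = 4,
                       learning_rate = 3e-4, weight_decay = 1e-4,
                       patience = 50,
                       n_patients = 60, patient_split_fraction = 0.8,
                       n_tests = 6, noise_sd = 0.05,
                       n_neighbors = 15, min_dist = 0.1,
                       raster_resolution = 64, sigma = 2,
                       binarize_threshold = 1e-4, corr_threshold = 0.2,
                       top_k = 3, n_components = 3,
                       seed = 7, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

# Deterministic planted effect-size matrix: each test loads mainly on one
# bundle with a weaker secondary loading on the next.
planted_weights <- function(n_tests, n_bundles) {
  W <- matrix(0, n_tests, n_bundles)
  for (t in seq_len(n_tests)) {
    b1 <- (t - 1) %% n_bundles + 1
    b2 <- t %% n_bundles + 1
    W[t, b1] <- 8
    W[t, b2] <- 3
  }
  rownames(W) <- sprintf("test%02d", seq_len(n_tests))
  W
}

#' Generate the full synthetic study for a configuration
#'
#' Builds the grid, brain mask, bundles, normative tractograms, traversal
#' cache, network-training lesions with their oracle disconnectomes, the
#' patient lesions with oracle disconnectomes, and the planted score table.
#' A pure function of the configuration (including its seed).
#'
#' @param cfg a [run_config()].
#' @return List with all simulated objects.
#' @export
simulate_study <- function(cfg) {
  grid <- grid_spec(rep(cfg$grid_size, 3), cfg$voxel_size)
  mask <- make_brain_mask(grid, cfg$margin)
  bundles <- make_bundles(grid, cfg$n_bundles, seed = cfg$seed + 11,
                          margin = cfg$margin)
  tractograms <- lapply(seq_len(cfg$n_subjects), function(i)
    sample_subject_tractogram(bundles, grid, per_bundle = cfg$per_bundle,
                              jitter_sd = cfg$jitter_sd,
                              seed = cfg$seed + 100 + i,
                              subject_id = sprintf("subj%02d", i)))
  cache <- streamline_voxel_cache(tractograms, grid)
  train_lesions <- lapply(seq_len(cfg$n_train_pairs), function(i)
    make_lesion(mask, grid, cfg$lesion_radius, seed = cfg$seed + 1000 + i))
  train_oracle <- lapply(train_lesions, compute_disconnectome,
                         brain_mask = mask, cache = cache)
  patient_lesions <- lapply(seq_len(cfg$n_patients), function(i)
    make_lesion(mask, grid, cfg$lesion_radius, seed = cfg$seed + 50000 + i))
  patient_oracle <- lapply(patient_lesions, compute_disconnectome,
                           brain_mask = mask, cache = cache)
  truth <- cohort_truth(planted_weights(cfg$n_tests, cfg$n_bundles),
                        noise_sd = cfg$noise_sd, seed = cfg$seed + 77)
  scores <- make_scores(patient_lesions, tractograms, grid, truth,
                        cache = cache)
  list(grid = grid, mask = mask, bundles = bundles,
       tractograms = tractograms, cache = cache,
       train_lesions = train_lesions, train_oracle = train_oracle,
       patient_lesions = patient_lesions, patient_oracle = patient_oracle,
       truth = truth, scores = scores)
}

# One framework (conventional or deep): fit a morphospace on the reference
# maps, embed the patients, build localisation images, and run the
# score-prediction pipeline on a fixed patient split.
run_framework <- function(ref_maps, patient_maps, mask, scores, split, cfg) {
  ref_mat <- vectorize_maps(ref_maps, mask)
  ms <- fit_morphospace(ref_mat, n_neighbors = cfg$n_neighbors,
                        min_dist = cfg$min_dist, seed = cfg$seed + 31,
                        resolution = cfg$raster_resolution, sigma = cfg$sigma)
  pat_mat <- vectorize_maps(patient_maps, mask)
  coords <- embed_new(ms, pat_mat)
  loc <- lapply(seq_len(nrow(coords)), function(i)
    localisation_map(coords[i, ], ms))
  rep <- score_prediction_pipeline(
    loc[split$train], loc[split$val],
    scores$measured[split$train, , drop = FALSE],
    scores$measured[split$val, , drop = FALSE],
    scores$max_score, threshold = cfg$corr_threshold, top_k = cfg$top_k,
    n_components = cfg$n_components)
  list(morphospace = ms, coords = coords, localisation = loc, report = rep)
}

#' Run the full replication pipeline
#'
#' Executes, at the configured scale: phantom simulation, oracle
#' disconnectomes, U-Net training, deep-disconnectome prediction, the two
#' morphospace prediction frameworks (conventional and deep), and the
#' comparison statistics; returns (and optionally writes) a JSON-ready
#' report with every headline metric plus full provenance. Deterministic
#' for a fixed configuration.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return List with `report` (plain data, JSON-serializable), and the
#'   heavyweight intermediates (`study`, `trained`, `frameworks`).
#' @export
run_replication <- function(cfg = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "simulate"
  result <- tryCatch({
    say("[simulate] phantom cohort")
    study <- simulate_study(cfg)

    stage <- "train"
    say("[train] U-Net (%d pairs, %d epochs)", cfg$n_train_pairs, cfg$epochs)
    template <- average_template(study$train_oracle)
    mcfg <- model_config(grid_size = cfg$grid_size,
                         base_filters = cfg$base_filters,
                         voxel_size = cfg$voxel_size)
    net <- build_unet(mcfg, seed = cfg$seed + 3)
    tcfg <- train_config(batch_size = cfg$batch_size,
                         learning_rate = cfg$learning_rate,
                         weight_decay = cfg$weight_decay,
                         max_epochs = cfg$epochs,
                         early_stop_patience = min(cfg$patience, cfg$epochs),
                         seed = cfg$seed + 5)
    pairs <- lapply(seq_along(study$train_lesions), function(i)
      list(lesion = study$train_lesions[[i]]$data,
           target = study$train_oracle[[i]]$data))
    trained <- train_model(net, pairs, study$mask, template, tcfg)
    val_r2 <- vapply(trained$split$val, function(i) {
      d <- predict_deep_disconnectome(trained$net, study$train_lesions[[i]],
                                      template, study$mask)
      suppressWarnings(goodness_of_fit(d, study$train_oracle[[i]], study$mask))
    }, numeric(1))

    stage <- "predict"
    say("[predict] deep-disconnectomes for %d patients", cfg$n_patients)
    patient_deep <- lapply(study$patient_lesions, function(l)
      predict_deep_disconnectome(trained$net, l, template, study$mask))

    stage <- "compare-maps"
    pw <- cohort_pairwise_r2(patient_deep, study$patient_oracle, study$mask)
    bin_conv <- lapply(study$patient_oracle, binarize_disconnectome,
                       threshold = cfg$binarize_threshold)
    bin_deep <- lapply(patient_deep, binarize_disconnectome,
                       threshold = cfg$binarize_threshold)
    freq_conv <- frequency_map(bin_conv)
    freq_deep <- frequency_map(bin_deep)
    contrast <- frequency_contrast(freq_conv, freq_deep)

    stage <- "morphospace"
    say("[morphospace] two frameworks")
    split <- split_dataset(cfg$n_patients, cfg$patient_split_fraction,
                           seed = cfg$seed + 13)
    fw_conv <- run_framework(study$train_oracle, study$patient_oracle,
                             study$mask, study$scores, split, cfg)
    deep_ref <- lapply(seq_along(study$train_lesions), function(i)
      predict_deep_disconnectome(trained$net, study$train_lesions[[i]],
                                 template, study$mask))
    fw_deep <- run_framework(deep_ref, patient_deep,
                             study$mask, study$scores, split, cfg)

    stage <- "compare-frameworks"
    ok <- !fw_conv$report$per_test$skipped & !fw_deep$report$per_test$skipped
    tt <- if (sum(ok) >= 3) {
      compare_frameworks(fw_deep$report$per_test$r2_test[ok],
                         fw_conv$report$per_test$r2_test[ok])
    } else list(t = NA_real_, df = NA_real_, p = NA_real_, mean_diff = NA_real_)
    dp_conv <- distance_profile(fw_conv$coords)
    dp_deep <- distance_profile(fw_deep$coords)
    ba <- bland_altman(as.numeric(dp_conv), as.numeric(dp_deep))

    report <- list(
      config = cfg[setdiff(names(cfg), "out_dir")],
      unet = list(best_epoch = attr(trained$history, "best_epoch"),
                  final_train_loss = utils::tail(trained$history$train_loss, 1),
                  best_val_loss = min(trained$history$val_loss),
                  mean_val_r2 = mean(val_r2, na.rm = TRUE),
                  n_val = length(val_r2)),
      map_comparison = list(mean_pairwise_r2 = pw$mean,
                            n_excluded = pw$n_excluded,
                            contrast_range = range(contrast)),
      frameworks = list(
        conventional = fw_conv$report$per_test,
        deep = fw_deep$report$per_test,
        conventional_mean_r2_test = fw_conv$report$mean_r2_test,
        deep_mean_r2_test = fw_deep$report$mean_r2_test,
        conventional_mean_accuracy_test = fw_conv$report$mean_accuracy_test,
        deep_mean_accuracy_test = fw_deep$report$mean_accuracy_test,
        conventional_mean_r2_train = fw_conv$report$mean_r2_train,
        deep_mean_r2_train = fw_deep$report$mean_r2_train,
        paired_t = tt),
      morphospace_distance = list(bland_altman = list(
        mean = ba$mean, sd = ba$sd, limits = as.list(ba$limits),
        ci = as.list(ba$ci), n = ba$n)))

    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(as.data.frame(trained$history),
                       file.path(cfg$out_dir, "history.csv"), row.names = FALSE)
      write_volume(contrast, study$grid,
                   file.path(cfg$out_dir, "frequency_contrast.nii.gz"))
      write_scores(study$scores, file.path(cfg$out_dir, "scores.csv"))
    }
    list(report = report, study = study, trained = trained,
         frameworks = list(conventional = fw_conv, deep = fw_deep),
         patient_deep = patient_deep)
  }, error = function(e) {
    stop(sprintf("replication failed at stage '%s': %s", stage,
                 conditionMessage(e)))
  })
  result
}

#' Scaled-down reconstruction-fidelity experiment
#'
#' The package's reference fidelity run: generate a synthetic cohort
#' (bundles, normative tractograms, lesions with oracle disconnectomes),
#' train the dual-channel U-Net on an 80/20 split with the standard loss
#' and optimizer settings, and measure the mean per-pair in-mask squared
#' Pearson correlation between predicted and oracle disconnectomes on the
#' held-out validation split.
#'
#' @param seed integer seed for every stage.
#' @param n_pairs lesion/disconnectome pairs (default 256).
#' @param epochs training epoch cap (default 60).
#' @param grid_size,base_filters network profile (defaults 16, 4).
#' @param verbose print training progress.
#' @return List: `mean_r2`, `per_pair_r2`, `n_val`, `history`, plus the
#'   `trained` model and simulation pieces for reuse.
#' @export
unet_fidelity_experiment <- function(seed = 1, n_pairs = 256, epochs = 60,
                                     grid_size = 16, base_filters = 4,
                                     verbose = FALSE) {
  cfg <- run_config(grid_size = grid_size, base_filters = base_filters,
                    n_train_pairs = n_pairs, epochs = epochs,
                    n_patients = 1, seed = seed)
  grid <- grid_spec(rep(cfg$grid_size, 3), cfg$voxel_size)
  mask <- make_brain_mask(grid, cfg$margin)
  bundles <- make_bundles(grid, cfg$n_bundles, seed = cfg$seed + 11,
                          margin = cfg$margin)
  tracts <- lapply(seq_len(cfg$n_subjects), function(i)
    sample_subject_tractogram(bundles, grid, per_bundle = cfg$per_bundle,
                              jitter_sd = cfg$jitter_sd,
                              seed = cfg$seed + 100 + i,
                              subject_id = sprintf("subj%02d", i)))
  cache <- streamline_voxel_cache(tracts, grid)
  lesions <- lapply(seq_len(n_pairs), function(i)
    make_lesion(mask, grid, cfg$lesion_radius, seed = cfg$seed + 1000 + i))
  oracle <- lapply(lesions, compute_disconnectome, brain_mask = mask,
                   cache = cache)
  template <- average_template(oracle)
  net <- build_unet(model_config(grid_size = grid_size,
                                 base_filters = base_filters,
                                 voxel_size = cfg$voxel_size),
                    seed = cfg$seed + 3)
  tcfg <- train_config(max_epochs = epochs,
                       early_stop_patience = min(50L, epochs),
                       seed = cfg$seed + 5)
  pairs <- lapply(seq_len(n_pairs), function(i)
    list(lesion = lesions[[i]]$data, target = oracle[[i]]$data))
  trained <- train_model(net, pairs, mask, template, tcfg, verbose = verbose)
  per_pair <- vapply(trained$split$val, function(i) {
    d <- predict_deep_disconnectome(trained$net, lesions[[i]], template, mask)
    suppressWarnings(goodness_of_fit(d, oracle[[i]], mask))
  }, numeric(1))
  ok <- is.finite(per_pair)
  list(mean_r2 = mean(per_pair[ok]), per_pair_r2 = per_pair,
       n_val = length(per_pair), history = trained$history,
       trained = trained, lesions = lesions, oracle = oracle,
       template = template, mask = mask, grid = grid)
}
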