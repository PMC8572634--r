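#' Default pipeline configuration
#'
#' A nested list mirroring the stage structure: phantom cohort, split sizes
#' (whole phantoms, never slices, so no leakage between train and
#' validation), preprocessing, model, training and evaluation settings.
#' Values can be overridden by a named list of `section$key` entries or a
#' YAML file with the same structure.
#'
#' @param overrides named list merged over the defaults (nested).
#' @return config list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    cohort = list(n_train = 24L, n_val = 6L, n_test = 12L,
                  volume_shape = c(64L, 64L, 64L), spacing_mm = 1.0,
                  noise_sd = 20, bias_field_amplitude = 0.1,
                  variation_freqs = list(Aco = 0.4, Pco = 0.6, P1 = 0.15,
                                         A1 = 0.1)),
    preprocess = list(target_spacing = 1.0, window = c(0, 2000),
                      patch_side = 64L, drop_empty = TRUE,
                      slices_per_volume = 12L),
    model = list(levels = 4L, base_filters = 4L, heads = "multitask"),
    train = list(learning_rate = 1e-3, epochs = 6L, batch_size = 8L,
                 augment = TRUE),
    evaluate = list(threshold = 0.5,
                    detection_segments = c("P1", "Pco", "Aco", "A1"))
  )
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  if (!is.null(overrides)) cfg <- merge_lists(cfg, overrides)
  cfg
}

# preprocess one phantom into (volume, mask) at the pipeline's working grid,
# then to a training patch set (optionally subsampled to a slice budget)
phantom_to_patches <- function(ph, pp, id, subsample_seed = NULL) {
  v <- resample_isotropic(ph$volume, pp$target_spacing, "linear")
  m <- resample_isotropic(ph$mask, pp$target_spacing, "nearest")
  v <- window_intensity(v, pp$window[1], pp$window[2])
  ps <- extract_patches(v, m, side = pp$patch_side,
                        drop_empty = isTRUE(pp$drop_empty), volume_id = id)
  budget <- pp$slices_per_volume
  if (!is.null(budget) && length(ps$patches) > budget) {
    keep <- if (is.null(subsample_seed))
      round(seq(1, length(ps$patches), length.out = budget))
    else with_seed(subsample_seed, sort(sample.int(length(ps$patches), budget)))
    ps$patches <- ps$patches[keep]
    ps$masks <- ps$masks[keep]
    ps$provenance <- ps$provenance[keep, ]
  }
  ps
}

# preprocessed volume pair for inference
phantom_to_volume <- function(ph, pp) {
  v <- resample_isotropic(ph$volume, pp$target_spacing, "linear")
  window_intensity(v, pp$window[1], pp$window[2])
}

#' Run the full simulate / preprocess / train / predict / evaluate pipeline
#'
#' Generates a phantom cohort, splits it by whole phantom into train /
#' validation / test, trains the configured network, segments the held-out
#' volumes and writes Dice and per-segment detection reports plus a run
#' manifest (config hash, seed, package version) into `out_dir`.
#'
#' A completed run directory (valid manifest with matching config hash and
#' all reports present) is resumed by returning its reports without
#' recomputation; a corrupted or mismatching manifest aborts.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return list with `manifest`, `history`, `dice_report`,
#'   `detection_report`, and the output paths.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("cowrun"),
                         quiet = TRUE) {
  for (key in c("seed", "cohort", "preprocess", "model", "train", "evaluate"))
    if (is.null(cfg[[key]])) stop("missing config key: ", key)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("reports"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  man_path0 <- file.path(out_dir, "manifest.json")
  tmp_cfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp_cfg)
  cfg_hash <- unname(tools::md5sum(tmp_cfg))
  report_files <- file.path(out_dir, "reports",
                            c("cohort_truth.csv", "training_history.csv",
                              "dice_validation.csv", "detection_accuracy.csv"))
  if (file.exists(man_path0)) {
    old <- tryCatch(jsonlite::read_json(man_path0),
                    error = function(e) NULL)
    if (is.null(old) || is.null(old$config_hash))
      stop("corrupted manifest: refusing to resume ", out_dir)
    if (!identical(old$config_hash, cfg_hash))
      stop("manifest config hash does not match this config: ",
           "refusing to resume ", out_dir)
    if (all(file.exists(report_files))) {
      if (!quiet) message("resuming completed run in ", out_dir)
      return(list(manifest = old,
                  history = read.csv(report_files[2]),
                  dice_report = read.csv(report_files[3]),
                  detection_report = read.csv(report_files[4]),
                  net = NULL,
                  paths = list(out_dir = out_dir, manifest = man_path0,
                               dice = report_files[3],
                               detection = report_files[4],
                               truth = report_files[1],
                               history = report_files[2])))
    }
  }
  file.copy(tmp_cfg, cfg_path, overwrite = TRUE)
  manifest <- list(seed = cfg$seed,
                   config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("cowseg")),
                   r_version = as.character(getRversion()))

  seeds <- derive_seeds(cfg$seed, 4L)
  co <- cfg$cohort
  base <- phantom_spec(volume_shape = co$volume_shape,
                       spacing_mm = co$spacing_mm, noise_sd = co$noise_sd,
                       bias_field_amplitude = co$bias_field_amplitude)
  ntot <- co$n_train + co$n_val + co$n_test
  if (!quiet) message("simulating ", ntot, " phantoms")
  cohort <- generate_cohort(ntot, variation_freqs = co$variation_freqs,
                            seed = seeds[1], base_spec = base)
  idx_train <- seq_len(co$n_train)
  idx_val <- co$n_train + seq_len(co$n_val)
  idx_test <- co$n_train + co$n_val + seq_len(co$n_test)

  truth_path <- file.path(out_dir, "reports", "cohort_truth.csv")
  write.csv(cohort_truth_table(cohort), truth_path, row.names = FALSE)

  if (!quiet) message("extracting patches")
  pp <- cfg$preprocess
  sub_seeds <- derive_seeds(seeds[2], co$n_train)
  train_ps <- c_patchsets(lapply(seq_along(idx_train), function(j)
    phantom_to_patches(cohort[[idx_train[j]]], pp, paste0("train", j),
                       sub_seeds[j])))

  if (!quiet) message("training on ", length(train_ps$patches), " patches")
  mc <- model_config(levels = cfg$model$levels,
                     base_filters = cfg$model$base_filters,
                     heads = cfg$model$heads)
  net <- build_model(mc, seed = seeds[3])
  tc <- train_config(learning_rate = cfg$train$learning_rate,
                     epochs = cfg$train$epochs,
                     batch_size = cfg$train$batch_size, seed = seeds[4],
                     augment = isTRUE(cfg$train$augment))
  fit <- train(net, train_ps, tc, quiet = quiet)
  hist_path <- file.path(out_dir, "reports", "training_history.csv")
  write.csv(fit$history, hist_path, row.names = FALSE)

  if (!quiet) message("segmenting held-out volumes")
  thr <- cfg$evaluate$threshold
  predict_set <- function(idx) lapply(idx, function(i) {
    pv <- phantom_to_volume(cohort[[i]], pp)
    predict_volume(fit$net, pv, thr)$mask
  })
  val_pred <- predict_set(idx_val)
  test_pred <- predict_set(idx_test)

  val_truth <- lapply(idx_val, function(i)
    resample_isotropic(cohort[[i]]$mask, pp$target_spacing, "nearest"))
  dice_report <- data.frame(
    case = idx_val,
    dice = vapply(seq_along(idx_val), function(j)
      dice_coefficient(val_pred[[j]], val_truth[[j]])$dice, numeric(1)))
  dice_path <- file.path(out_dir, "reports", "dice_validation.csv")
  write.csv(dice_report, dice_path, row.names = FALSE)

  det <- vapply(cfg$evaluate$detection_segments, function(sg)
    segment_detection_accuracy(test_pred, cohort[idx_test], sg), numeric(1))
  detection_report <- data.frame(segment = cfg$evaluate$detection_segments,
                                 accuracy = unname(det))
  det_path <- file.path(out_dir, "reports", "detection_accuracy.csv")
  write.csv(detection_report, det_path, row.names = FALSE)

  manifest$mean_val_dice <- mean(dice_report$dice)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)

  list(manifest = manifest, history = fit$history, dice_report = dice_report,
       detection_report = detection_report, net = fit$net,
       paths = list(out_dir = out_dir, manifest = man_path,
                    dice = dice_path, detection = det_path,
                    truth = truth_path, history = hist_path))
}
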