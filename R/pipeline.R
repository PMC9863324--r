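#' Generate a cohort of phantom exams
#'
#' Draws per-exam vessel sizes, pulsation amplitudes and blood pressures
#' from ranges typical of a dilated ascending aorta, and renders one
#' phantom per exam. Used to build training/evaluation corpora with known
#' truth.
#'
#' @param n number of exams.
#' @param grid_size,pixel_spacing,n_frames as in [phantom_config()].
#' @param seed integer master seed; exam `i` uses `seed * 1000 + i` for its
#'   rendering so cohorts are reproducible exam by exam.
#' @param artifact_level,noise_sd,neighbor_structures passed through.
#' @param rotation_deg quadrant offset for the analytic truth.
#' @return List of exams: `list(cine, masks, truth, pressures)` each.
#' @export
phantom_cohort <- function(n, grid_size = 256L, pixel_spacing = 1.17,
                           n_frames = 30L, seed = 1L, artifact_level = 0.3,
                           noise_sd = 0.03, neighbor_structures = TRUE,
                           rotation_deg = 60) {
  draws <- with_seed(seed, {
    data.frame(a = stats::runif(n, 16, 26),
               ab_ratio = stats::runif(n, 0.82, 1.0),
               pf = stats::runif(n, 0.05, 0.12),
               sys = round(stats::runif(n, 105, 150)),
               pulse = round(stats::runif(n, 30, 60)))
  })
  lapply(seq_len(n), function(i) {
    pr <- pressure_pair(draws$sys[i], draws$sys[i] - draws$pulse[i])
    cfg <- phantom_config(
      grid_size = grid_size, pixel_spacing = pixel_spacing,
      n_frames = n_frames,
      semi_axes_dia = c(draws$a[i], draws$a[i] * draws$ab_ratio[i]),
      pulsation_fraction = draws$pf[i], noise_sd = noise_sd,
      artifact_level = artifact_level,
      neighbor_structures = neighbor_structures, pressures = pr,
      seed = seed * 1000L + i)
    ph <- generate_phantom(cfg, rotation_deg = rotation_deg,
                           exam_id = sprintf("phantom_%03d", i))
    ph$pressures <- pr
    ph
  })
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()]: where data comes from (a generated
#' phantom cohort or a directory of saved sequences), how the model is
#' obtained (train or load a checkpoint), and which analyses to run.
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param seed master seed propagated to every stochastic stage.
#' @param rotation_deg quadrant offset in degrees.
#' @param n_exams,n_test phantom cohort size and held-out test exams.
#' @param grid_size,n_frames,pixel_spacing phantom geometry.
#' @param unet a [unet_config()]; defaults to [unet_desk_profile()].
#' @param train a [train_config()] or `NULL` to skip training (requires
#'   `checkpoint`).
#' @param cross_validate run the full K-fold protocol during training.
#' @param checkpoint path to a saved model to load instead of training.
#' @param tensile a [tensile_sim_config()], a list of them, or paths to
#'   tensile CSV records; `NULL` skips the ex-vivo stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, rotation_deg = 60,
                            n_exams = 12L, n_test = 2L, grid_size = 128L,
                            n_frames = 6L, pixel_spacing = 1.17,
                            unet = unet_desk_profile(),
                            train = train_config(max_epochs = 8L,
                                                 batch_size = 4L),
                            cross_validate = FALSE, checkpoint = NULL,
                            tensile = tensile_sim_config()) {
  stop_if(is.null(train) && is.null(checkpoint),
          "either a train config or a checkpoint is required")
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 rotation_deg = rotation_deg, n_exams = as.integer(n_exams),
                 n_test = as.integer(n_test), grid_size = as.integer(grid_size),
                 n_frames = as.integer(n_frames),
                 pixel_spacing = pixel_spacing, unet = unet, train = train,
                 cross_validate = isTRUE(cross_validate),
                 checkpoint = checkpoint, tensile = tensile),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Generates (or loads) the data, preprocesses it, trains or loads the
#' segmentation model, segments the held-out exams, evaluates the
#' segmentation against ground truth, computes global and quadrant-local
#' compliance and strain from the predicted masks, analyzes the tensile
#' records, and writes agreement statistics between predicted and
#' ground-truth elastic measurements. Every artifact, the exact
#' configuration and a run log are written to `output_dir`; re-running
#' with the same configuration reproduces the outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return List with `model`, `metrics`, `reports` (per test exam,
#'   predicted and truth-mask elasticity), `agreement`, `tensile`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("seed: %d", config$seed)
  yaml::write_yaml(pipeline_config_to_list(config),
                   file.path(out, "config.yaml"))

  say <- function(...) if (verbose) message(sprintf(...))
  say("generating %d phantom exams", config$n_exams)
  cohort <- phantom_cohort(config$n_exams, grid_size = config$grid_size,
                           n_frames = config$n_frames,
                           pixel_spacing = config$pixel_spacing,
                           seed = config$seed,
                           rotation_deg = config$rotation_deg)
  target <- config$unet$input_size
  exams <- lapply(cohort, function(ph) {
    list(cine = preprocess_sequence(ph$cine, target = target),
         masks = preprocess_masks(ph$masks, target = target))
  })
  test_idx <- with_seed(config$seed,
                        sample.int(length(exams), config$n_test))
  log_line("test exams: %s", paste(test_idx, collapse = ","))

  if (!is.null(config$checkpoint)) {
    model <- load_model(config$checkpoint)
    say("loaded checkpoint %s", config$checkpoint)
  } else {
    say("training on %d exams", length(exams) - config$n_test)
    cfg <- config$train
    cfg$seed <- config$seed
    model <- train_unet(exams[-test_idx], config$unet, cfg,
                        cross_validate = config$cross_validate,
                        verbose = verbose)
    save_model(model, file.path(out, "model.rds"))
    write_training_log(model, file.path(out, "training_log.csv"))
  }

  metrics <- list(); reports <- list()
  pred_rows <- list(); truth_rows <- list()
  for (i in test_idx) {
    ph <- cohort[[i]]
    pred <- predict_mask(model, exams[[i]]$cine)
    m <- segmentation_metrics(pred, exams[[i]]$masks,
                              spacing = config$pixel_spacing)
    metrics[[ph$cine$exam_id]] <- m
    write_segmentation_metrics(m, file.path(out, ph$cine$exam_id))
    rep_pred <- elasticity_report(pred, ph$pressures,
                                  spacing = config$pixel_spacing,
                                  rotation_deg = config$rotation_deg)
    rep_truth <- elasticity_report(exams[[i]]$masks, ph$pressures,
                                   spacing = config$pixel_spacing,
                                   rotation_deg = config$rotation_deg)
    write_elasticity_report(rep_pred,
                            file.path(out, paste0(ph$cine$exam_id, "_pred")),
                            curves = TRUE)
    reports[[ph$cine$exam_id]] <- list(predicted = rep_pred,
                                       truth_masks = rep_truth,
                                       truth = ph$truth)
    pred_rows[[length(pred_rows) + 1]] <-
      data.frame(min_area = rep_pred$min_area, max_area = rep_pred$max_area,
                 compliance = rep_pred$global_compliance)
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(min_area = min(ph$truth$area_per_frame),
                 max_area = max(ph$truth$area_per_frame),
                 compliance = ph$truth$true_compliance)
  }

  agreement <- NULL
  if (length(pred_rows) >= 3) {
    agreement <- agreement_table(do.call(rbind, pred_rows),
                                 do.call(rbind, truth_rows))
    utils::write.csv(agreement, file.path(out, "agreement.csv"),
                     row.names = FALSE)
  }

  tens <- NULL
  if (!is.null(config$tensile)) {
    specs <- if (inherits(config$tensile, "tensile_sim_config") ||
                 is.character(config$tensile)) list(config$tensile)
    else config$tensile
    tens <- lapply(specs, function(s) {
      rec <- if (is.character(s)) read_tensile_record(s) else generate_tensile(s)
      mr <- modulus_curve(stress_strain_curve(rec))
      mr
    })
    jsonlite::write_json(
      lapply(tens, function(mr) list(E_max_MPa = mr$E_max,
                                     method = mr$method)),
      file.path(out, "tensile.json"), auto_unbox = TRUE, digits = NA)
  }

  mean_dice <- mean(vapply(metrics, function(m)
    m$aggregate$mean[m$aggregate$metric == "dice"], 0))
  log_line("held-out mean Dice: %.4f", mean_dice)
  say("held-out mean Dice: %.4f", mean_dice)
  list(model = model, metrics = metrics, reports = reports,
       agreement = agreement, tensile = tens, mean_dice = mean_dice,
       test_idx = test_idx)
}

pipeline_config_to_list <- function(config) {
  lst <- unclass(config)
  lst$unet <- unclass(lst$unet)
  if (!is.null(lst$train)) lst$train <- unclass(lst$train)
  if (inherits(lst$tensile, "tensile_sim_config")) {
    ts <- unclass(lst$tensile)
    ts$modulus_segments <- as.list(ts$modulus_segments)
    lst$tensile <- ts
  }
  lst
}
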