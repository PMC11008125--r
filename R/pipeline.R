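#' Default run configuration
#'
#' One nested, YAML-serializable list drives the whole pipeline; every run
#' writes its resolved configuration beside its outputs, and a single global
#' seed derives fixed per-stage seeds so stages can be re-run in isolation.
#'
#' @param seed global seed.
#' @param scene named list of [scene_spec()] arguments.
#' @param protocol named list of [oxygen_protocol()] arguments.
#' @param expected_diameter segmentation diameter parameter in pixels.
#' @param train named list: `n_per_class`, `input_size`, `epochs`,
#'   `batch_size`, `lr`.
#' @param max_displacement tracking gate in pixels.
#' @param smoothing_window,persistence kinetics parameters (frames).
#' @param model_path optional path to a saved model; skips the training
#'   stage.
#' @return nested configuration list.
#' @export
run_config <- function(seed = 1L, scene = list(), protocol = list(),
                       expected_diameter = 90,
                       train = list(n_per_class = 400, input_size = 64,
                                    epochs = 8, batch_size = 32, lr = 0.001),
                       max_displacement = 15, smoothing_window = 3L,
                       persistence = 3L, model_path = NULL) {
  list(seed = as.integer(seed), scene = scene, protocol = protocol,
       expected_diameter = expected_diameter, train = train,
       max_displacement = max_displacement,
       smoothing_window = smoothing_window, persistence = persistence,
       model_path = model_path)
}

#' Analyze a frame sequence end to end (in memory)
#'
#' Chains segmentation, optional shape-factor extraction, classification,
#' tracking, the sickled-fraction curve and per-cell delay times.
#'
#' @param frames list of `labeled_frame` objects (the `label_mask` fields
#'   are ignored; segmentation is recomputed).
#' @param model trained `sickle_cnn` (or a `cnn_fit`, whose best checkpoint
#'   is used).
#' @param protocol the [oxygen_protocol()] of the recording.
#' @param expected_diameter segmentation diameter in pixels.
#' @param compute_factors also extract the nine morphometric factors.
#' @param max_displacement,smoothing_window,persistence see the kinetics
#'   functions.
#' @param adapter optional external segmenter.
#' @return list: `records`, `discards`, `predictions`, `tracks`, `curve`,
#'   `delays`, and `features` when requested.
#' @export
analyze_sequence <- function(frames, model, protocol,
                             expected_diameter = 90, compute_factors = FALSE,
                             max_displacement = 15, smoothing_window = 3L,
                             persistence = 3L, adapter = NULL) {
  if (inherits(model, "cnn_fit")) model <- model$model
  seg <- segment_sequence(frames, expected_diameter, adapter = adapter)
  if (!length(seg$records))
    stopf("no cells segmented in any frame")
  pred <- predict_cells(model, seg$records)
  pred$x <- vapply(seg$records, function(r) r$centroid[1], numeric(1))
  pred$y <- vapply(seg$records, function(r) r$centroid[2], numeric(1))
  tracks <- link_tracks(pred, max_displacement)
  curve <- sickled_fraction_curve(tracks, smoothing_window, protocol)
  delays <- delay_times(tracks, protocol, persistence, smoothing_window)
  out <- list(records = seg$records, discards = seg$discards,
              predictions = pred, tracks = tracks, curve = curve,
              delays = delays)
  if (compute_factors) out$features <- shape_factor_table(seg$records)
  out
}

stage_done <- function(dir, files) all(file.exists(file.path(dir, files)))

#' Run the full pipeline into an output directory
#'
#' Stages run in order simulate, segment, features, train, classify,
#' kinetics; each writes plain-file intermediates (PNG/CSV/YAML) so it is
#' independently inspectable, and with `resume = TRUE` stages whose outputs
#' already exist are skipped.
#'
#' @param config from [run_config()].
#' @param out_dir run directory (created).
#' @param resume skip stages with existing outputs.
#' @param quiet suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir, resume = FALSE,
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  protocol <- do.call(oxygen_protocol, config$protocol)

  frames_dir <- file.path(out_dir, "frames")
  if (!(resume && length(list.files(frames_dir, pattern = "^frame_")))) {
    scene_args <- config$scene
    scene_args$seed <- derive_seed(config$seed, 11L)
    scn <- do.call(scene_spec, scene_args)
    say("simulate: %d cells, %d frames", scn$n_cells, length(frame_times(protocol)))
    sq <- generate_sequence(scn, protocol)
    write_sequence(sq, frames_dir)
  } else say("simulate: resumed")
  frames <- read_sequence_frames(frames_dir)

  seg_dir <- file.path(out_dir, "segmentation")
  dir.create(seg_dir, showWarnings = FALSE)
  seg <- segment_sequence(frames, config$expected_diameter)
  say("segment: %d records, %d discards", length(seg$records), nrow(seg$discards))
  utils::write.csv(seg$discards, file.path(seg_dir, "discards.csv"), row.names = FALSE)
  recs_df <- data.frame(
    cell_label = vapply(seg$records, `[[`, integer(1), "cell_label"),
    frame = vapply(seg$records, `[[`, integer(1), "frame_index"),
    t = vapply(seg$records, `[[`, numeric(1), "t"),
    x = vapply(seg$records, function(r) r$centroid[1], numeric(1)),
    y = vapply(seg$records, function(r) r$centroid[2], numeric(1)))
  utils::write.csv(recs_df, file.path(seg_dir, "records.csv"), row.names = FALSE)

  feat_file <- file.path(out_dir, "features.csv")
  if (!(resume && file.exists(feat_file))) {
    feats <- shape_factor_table(seg$records)
    utils::write.csv(feats, feat_file, row.names = FALSE)
    say("features: %d rows", if (is.null(feats)) 0L else nrow(feats))
  } else say("features: resumed")

  model_file <- file.path(out_dir, "model.rds")
  if (!is.null(config$model_path)) {
    fit <- load_cnn(config$model_path)
  } else if (resume && file.exists(model_file)) {
    fit <- load_cnn(model_file)
    say("train: resumed")
  } else {
    tc <- config$train
    say("train: %d patches/class, %d epochs", tc$n_per_class, tc$epochs)
    ds <- sample_patch_dataset(tc$n_per_class, patch_size = tc$input_size,
                               protocol = protocol,
                               seed = derive_seed(config$seed, 12L))
    model <- build_cnn(cnn_architecture(), input_size = tc$input_size,
                       seed = derive_seed(config$seed, 13L))
    fit <- train_cnn(model, ds$x, ds$y,
                     config = train_config(epochs = tc$epochs,
                                           batch_size = tc$batch_size,
                                           lr = tc$lr,
                                           seed = derive_seed(config$seed, 14L)))
    save_cnn(fit, model_file)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  model <- if (inherits(fit, "cnn_fit")) fit$model else fit

  pred <- predict_cells(model, seg$records)
  pred$x <- recs_df$x; pred$y <- recs_df$y
  utils::write.csv(pred, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  say("classify: %d predictions", nrow(pred))

  tracks <- link_tracks(pred, config$max_displacement)
  curve <- sickled_fraction_curve(tracks, config$smoothing_window, protocol)
  delays <- delay_times(tracks, protocol, config$persistence,
                        config$smoothing_window)
  utils::write.csv(as.data.frame(curve), file.path(out_dir, "curve.csv"),
                   row.names = FALSE)
  utils::write.csv(delays, file.path(out_dir, "delays.csv"), row.names = FALSE)
  say("kinetics: %d tracks, initial sickled fraction %.3f",
      length(unique(tracks$track_id)), curve$fraction[1])
  invisible(out_dir)
}
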