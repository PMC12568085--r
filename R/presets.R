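#' Per-dataset pipeline presets
#'
#' Bundles the filter, normalization, augmentation and training settings
#' used for the three dataset styles: `"katakana"` (EOG, 125 Hz, filters
#' on, distortion gap 32), `"eog_arabic"` (EOG, 64 Hz, filters on, gap 64,
#' minimum learning rate 1e-6) and `"webcam"` (no filters, gap 32). All
#' share target length M = 64, distortion presets I (mean 1.0, variance
#' 0.1) and II (mean 1.01, variance 0.01), window warping with ratio 0.3
#' and scales {0.25, 4}, 400 epochs, batch 512, weight decay 0.1, AMSGrad,
#' maximum learning rate 0.001 and a 16-epoch cosine period.
#'
#' @param dataset One of `"webcam"`, `"katakana"`, `"eog_arabic"`.
#' @param n_classes Number of classes (10 for the numeral protocols, 12 for
#'   Katakana-style strokes; defaults accordingly).
#' @return A list with `filter_cfg`, `norm_cfg`, `augment`, `model_cfg`,
#'   `train_cfg`.
#' @export
pipeline_preset <- function(dataset = c("webcam", "katakana", "eog_arabic"),
                            n_classes = NULL) {
  dataset <- match.arg(dataset)
  gap <- if (dataset == "eog_arabic") 64L else 32L
  filter_cfg <- switch(dataset,
    webcam = filter_config(enabled = FALSE),
    katakana = filter_config(sampling_rate_hz = 125, cutoff_hz = 10,
                             lowpass_order = 5),
    eog_arabic = filter_config(sampling_rate_hz = 64, cutoff_hz = 10,
                               lowpass_order = 5))
  n_classes <- n_classes %||% if (dataset == "katakana") 12L else 10L
  list(
    filter_cfg = filter_cfg,
    norm_cfg = normalization_config(target_length = 64),
    augment = list(distortion1 = distortion_config(1.0, 0.1, gap),
                   distortion2 = distortion_config(1.01, 0.01, gap),
                   warp = warp_config(0.3, c(0.25, 4.0))),
    model_cfg = model_config(input_length = 64, n_classes = n_classes),
    train_cfg = train_config(lr_min = if (dataset == "eog_arabic") 1e-6 else 0))
}

#' Load a pipeline configuration from a YAML run config
#'
#' Reads the keys `preprocess.filters.*`, `preprocess.target_length`,
#' `preprocess.amplitude_mode`, `preprocess.baseline_pad_length`,
#' `preprocess.initial_point`, `augment.*`, `model.*`, `train.*` and
#' `generate.*`, falling back to package defaults for anything absent.
#'
#' @param path Path to a YAML file.
#' @return A list with `filter_cfg`, `norm_cfg`, `augment`, `model_cfg`,
#'   `train_cfg` and (when a `generate` block exists) `generator_cfg`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- y$preprocess %||% list()
  fl <- pp$filters %||% list()
  filter_cfg <- filter_config(
    median_window = fl$median_window %||% 5,
    lowpass_order = fl$lowpass_order %||% 5,
    cutoff_hz = fl$cutoff_hz %||% 10,
    sampling_rate_hz = fl$sampling_rate_hz %||% 125,
    dc_pole = fl$dc_pole %||% 0.995,
    enabled = fl$enabled %||% TRUE)
  norm_cfg <- normalization_config(
    target_length = pp$target_length %||% 64,
    amplitude_mode = pp$amplitude_mode %||% "preserve",
    baseline_pad_length = pp$baseline_pad_length,
    apply_initial_point = pp$initial_point %||% TRUE)
  au <- y$augment %||% list()
  mk_dist <- function(block, default_mean, default_var) {
    distortion_config(block$mean %||% default_mean,
                      block$variance %||% default_var,
                      block$gap %||% 32)
  }
  # `augment: false` (or "none") turns training-set augmentation off
  augment <- if (identical(au, FALSE) || identical(au, "none")) NULL else list(
    distortion1 = mk_dist(au$distortion1 %||% list(), 1.0, 0.1),
    distortion2 = mk_dist(au$distortion2 %||% list(), 1.01, 0.01),
    warp = warp_config((au$window_warp %||% list())$ratio %||% 0.3,
                       unlist((au$window_warp %||% list())$scales) %||% c(0.25, 4.0)))
  mo <- y$model %||% list()
  model_cfg <- model_config(
    input_length = mo$input_length %||% (norm_cfg$baseline_pad_length %||% norm_cfg$target_length),
    n_classes = mo$n_classes %||% 10,
    fusion = mo$fusion %||% "parallel",
    cnn = mo$cnn %||% list(), tcn = mo$tcn %||% list(),
    head = mo$head %||% list())
  tr <- y$train %||% list()
  train_cfg <- train_config(
    epochs = tr$epochs %||% 400, batch_size = tr$batch_size %||% 512,
    weight_decay = tr$weight_decay %||% 0.1, amsgrad = tr$amsgrad %||% TRUE,
    lr_max = tr$lr_max %||% 0.001, lr_min = tr$lr_min %||% 0,
    cosine_period = tr$cosine_period %||% 16,
    schedule_unit = tr$schedule_unit %||% "epoch",
    seed = tr$seed %||% y$seed %||% 1)
  out <- list(filter_cfg = filter_cfg, norm_cfg = norm_cfg, augment = augment,
              model_cfg = model_cfg, train_cfg = train_cfg)
  if (!is.null(y$generate)) {
    g <- y$generate
    out$generator_cfg <- generator_config(
      n_subjects = g$subjects %||% 19, patterns = g$patterns %||% "digits10",
      trials_per_pattern = g$trials %||% 5,
      sampling_rate_hz = g$sampling_rate_hz %||% 30,
      duration_range_s = unlist(g$duration_range_s) %||% c(1.69, 23.51),
      noise_sd = g$noise_sd %||% 0.01, spike_prob = g$spike_prob %||% 0,
      subject_offset_sd = g$subject_offset_sd %||% 0.1,
      subject_scale_sd = g$subject_scale_sd %||% 0.1,
      seed = g$seed %||% y$seed %||% 1)
  }
  out
}

#' Save / load model weights
#'
#' Serializes a fitted model together with its configuration fingerprint;
#' loading refuses a checkpoint whose fingerprint disagrees with the
#' supplied configuration.
#'
#' @param model An `eyw_model`.
#' @param path Checkpoint path (.rds).
#' @return `path` invisibly for save; an `eyw_model` for load.
#' @export
save_model <- function(model, path) {
  layers <- model_layers(model)
  weights <- lapply(layers, function(l) {
    c(mget(l$params, envir = l),
      if (l$type == "bn") list(run_mean = l$run_mean, run_var = l$run_var))
  })
  saveRDS(list(cfg = model$cfg, weights = weights,
               fingerprint = config_fingerprint(model$cfg)), path)
  invisible(path)
}

#' @rdname save_model
#' @param cfg The [model_config()] the checkpoint is expected to match.
#' @export
load_model <- function(path, cfg) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, config_fingerprint(cfg))) {
    abort("checkpoint fingerprint does not match the supplied configuration.")
  }
  model <- init_model(cfg, seed = 0L)
  layers <- model_layers(model)
  if (length(layers) != length(ck$weights)) abort("checkpoint layout mismatch.")
  for (i in seq_along(layers)) {
    for (nm in names(ck$weights[[i]])) {
      assign(nm, ck$weights[[i]][[nm]], envir = layers[[i]])
    }
  }
  model
}
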