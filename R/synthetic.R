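#' Configuration for the synthetic eye-writing generator
#'
#' Emulates the statistical structure of eye-writing data collection: each
#' sample traces a class-specific polyline template with per-subject
#' position/scale variability, per-segment speed jitter, additive fixation
#' noise, sporadic spike artifacts (blink/EOG-style transients that the
#' median filter is there to remove) and a recording duration drawn
#' uniformly from a wide range, so trajectory lengths vary strongly across
#' samples. Defaults model the webcam-style protocol: 19 subjects x 10
#' numeral patterns x 5 repetitions at 30 Hz (a typical webcam rate) with
#' durations spanning 1.69-23.51 s and no spikes.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param patterns `"digits10"` (10 single-stroke numerals) or
#'   `"katakana12"` (12 rectilinear Katakana-style strokes).
#' @param trials_per_pattern Repetitions per (subject, pattern) cell.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_range_s Length-2 vector (min, max) of recording
#'   durations in seconds.
#' @param noise_sd Standard deviation of additive Gaussian fixation noise,
#'   in the unit-square position units of the templates.
#' @param spike_prob Per-sample probability of a large transient spike
#'   (must lie in [0, 0.05]); use 0 for webcam-style data.
#' @param subject_offset_sd,subject_scale_sd Standard deviations of the
#'   per-subject position offset (additive) and scale (around 1).
#' @param seed Integer master seed; the generator is fully deterministic
#'   given the seed.
#' @return A list of class `eyw_generator_config`.
#' @export
generator_config <- function(n_subjects = 19, patterns = c("digits10", "katakana12"),
                             trials_per_pattern = 5, sampling_rate_hz = 30,
                             duration_range_s = c(1.69, 23.51), noise_sd = 0.01,
                             spike_prob = 0, subject_offset_sd = 0.1,
                             subject_scale_sd = 0.1, seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (trials_per_pattern < 1) abort("`trials_per_pattern` must be >= 1.")
  if (!(duration_range_s[1] > 0 && duration_range_s[1] <= duration_range_s[2])) {
    abort("need 0 < min duration <= max duration.")
  }
  if (spike_prob < 0 || spike_prob > 0.05) {
    abort("`spike_prob` must lie in [0, 0.05].")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 patterns = match.arg(patterns),
                 trials_per_pattern = as.integer(trials_per_pattern),
                 sampling_rate_hz = sampling_rate_hz,
                 duration_range_s = duration_range_s, noise_sd = noise_sd,
                 spike_prob = spike_prob,
                 subject_offset_sd = subject_offset_sd,
                 subject_scale_sd = subject_scale_sd, seed = as.integer(seed)),
            class = "eyw_generator_config")
}

#' Built-in pattern templates
#'
#' Class-specific single-stroke polylines in the unit square. `"digits10"`
#' returns stylised strokes for the numerals 0-9; `"katakana12"` returns 12
#' rectilinear Katakana-style strokes, the first of which traces
#' left, up, right, down, left. The templates are structurally analogous to
#' real eye-writing glyphs (distinct shapes, single strokes), not
#' reproductions of any particular glyph set.
#'
#' @param patterns `"digits10"` or `"katakana12"`.
#' @return A named list of matrices (vertex columns `x`, `y`), one per class.
#' @export
builtin_templates <- function(patterns = c("digits10", "katakana12")) {
  patterns <- match.arg(patterns)
  pl <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("x", "y")
    m
  }
  if (patterns == "digits10") {
    list(
      "0" = pl(0.5, 1, 0.15, 0.75, 0.15, 0.25, 0.5, 0, 0.85, 0.25, 0.85, 0.75, 0.5, 1),
      "1" = pl(0.3, 0.75, 0.5, 1, 0.5, 0),
      "2" = pl(0.15, 0.8, 0.35, 1, 0.65, 1, 0.85, 0.8, 0.85, 0.6, 0.15, 0, 0.85, 0),
      "3" = pl(0.15, 0.9, 0.6, 1, 0.85, 0.78, 0.5, 0.55, 0.85, 0.3, 0.6, 0, 0.15, 0.1),
      "4" = pl(0.7, 0, 0.7, 1, 0.15, 0.35, 0.9, 0.35),
      "5" = pl(0.85, 1, 0.2, 1, 0.2, 0.55, 0.6, 0.6, 0.85, 0.35, 0.6, 0, 0.2, 0.1),
      "6" = pl(0.75, 1, 0.3, 0.6, 0.2, 0.25, 0.5, 0, 0.8, 0.25, 0.55, 0.5, 0.25, 0.35),
      "7" = pl(0.15, 1, 0.85, 1, 0.4, 0),
      "8" = pl(0.5, 0.5, 0.2, 0.75, 0.5, 1, 0.8, 0.75, 0.2, 0.25, 0.5, 0, 0.8, 0.25, 0.5, 0.5),
      "9" = pl(0.8, 0.75, 0.5, 1, 0.2, 0.75, 0.5, 0.5, 0.8, 0.75, 0.8, 0.25, 0.55, 0))
  } else {
    list(
      # left, up, right, down, left
      K01 = pl(0.9, 0.45, 0.1, 0.45, 0.1, 0.85, 0.9, 0.85, 0.9, 0.15, 0.1, 0.15),
      K02 = pl(0.1, 0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 0.1),
      K03 = pl(0.1, 0.7, 0.9, 0.7, 0.9, 0.1, 0.1, 0.1),
      K04 = pl(0.5, 0.95, 0.5, 0.05, 0.1, 0.45, 0.9, 0.45),
      K05 = pl(0.1, 0.9, 0.9, 0.9, 0.1, 0.1, 0.9, 0.1),
      K06 = pl(0.9, 0.9, 0.1, 0.9, 0.1, 0.1, 0.9, 0.1, 0.9, 0.5),
      K07 = pl(0.1, 0.5, 0.9, 0.9, 0.9, 0.1),
      K08 = pl(0.1, 0.1, 0.5, 0.9, 0.9, 0.1, 0.5, 0.45),
      K09 = pl(0.1, 0.9, 0.5, 0.5, 0.1, 0.1, 0.9, 0.1),
      K10 = pl(0.9, 0.1, 0.1, 0.5, 0.9, 0.9, 0.5, 0.9),
      K11 = pl(0.1, 0.9, 0.9, 0.5, 0.1, 0.1),
      K12 = pl(0.5, 0.9, 0.1, 0.5, 0.5, 0.1, 0.9, 0.5, 0.5, 0.9))
  }
}

# Per-subject affine variability drawn once per subject.
subject_parameters <- function(cfg, subject_index) {
  set.seed(derive_seed(cfg$seed, "subject", subject_index))
  list(offset = rnorm(2, 0, cfg$subject_offset_sd),
       scale = rnorm(2, 1, cfg$subject_scale_sd))
}

#' Generate one synthetic eye-writing sample
#'
#' Draws a duration, traces the template polyline at piecewise-constant
#' speed with per-segment speed jitter, applies the subject's affine
#' (scale about the template centre plus offset), then adds fixation noise
#' and, with `spike_prob` per sample, large transient spikes.
#'
#' @param template A polyline matrix from [builtin_templates()].
#' @param subject_params List with `offset` (length 2) and `scale`
#'   (length 2), as drawn per subject by [generate_dataset()].
#' @param cfg An [generator_config()].
#' @param stream_seed Integer seed making this sample deterministic.
#' @return An `eyw_traj` with a `t` column at the configured sampling rate.
#' @export
generate_sample <- function(template, subject_params, cfg, stream_seed) {
  set.seed(stream_seed)
  fs <- cfg$sampling_rate_hz
  duration <- runif(1, cfg$duration_range_s[1], cfg$duration_range_s[2])
  n <- max(2L, as.integer(round(duration * fs)))
  nseg <- nrow(template) - 1L
  seg_len <- sqrt(rowSums((template[-1, , drop = FALSE] -
                           template[-nrow(template), , drop = FALSE])^2))
  # per-segment speed jitter: log-normal multipliers on the time spent
  jitter <- exp(rnorm(nseg, 0, 0.2))
  seg_time <- seg_len * jitter
  cum <- c(0, cumsum(seg_time)) / sum(seg_time)
  tfrac <- seq(0, 1, length.out = n)
  seg <- pmin(findInterval(tfrac, cum, rightmost.closed = TRUE), nseg)
  local <- (tfrac - cum[seg]) / (cum[seg + 1L] - cum[seg])
  pts <- template[seg, , drop = FALSE] +
    local * (template[seg + 1L, , drop = FALSE] - template[seg, , drop = FALSE])
  # subject affine about the unit-square centre
  pts[, 1] <- (pts[, 1] - 0.5) * subject_params$scale[1] + 0.5 + subject_params$offset[1]
  pts[, 2] <- (pts[, 2] - 0.5) * subject_params$scale[2] + 0.5 + subject_params$offset[2]
  if (cfg$noise_sd > 0) pts <- pts + matrix(rnorm(2 * n, 0, cfg$noise_sd), n, 2)
  if (cfg$spike_prob > 0) {
    hit <- runif(n) < cfg$spike_prob
    if (any(hit)) {
      k <- sum(hit)
      pts[hit, 1] <- pts[hit, 1] + sample(c(-1, 1), k, TRUE) * runif(k, 0.5, 1)
      pts[hit, 2] <- pts[hit, 2] + sample(c(-1, 1), k, TRUE) * runif(k, 0.5, 1)
    }
  }
  trajectory(pts[, 1], pts[, 2], t = (seq_len(n) - 1) / fs, sampling_rate = fs)
}

#' Generate a balanced synthetic eye-writing dataset
#'
#' Produces `n_subjects x n_patterns x trials_per_pattern` samples with
#' stable subject ids and per-sample random streams derived from the master
#' seed, so the bundle is reproducible and order-independent.
#'
#' @param cfg An [generator_config()].
#' @return An `eyw_bundle` of raw samples.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "eyw_generator_config"))
  templates <- builtin_templates(cfg$patterns)
  labels <- names(templates)
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  grid <- expand.grid(trial_index = seq_len(cfg$trials_per_pattern) - 1L,
                      label = labels, subject_id = subjects,
                      stringsAsFactors = FALSE)
  sp <- lapply(seq_len(cfg$n_subjects), function(i) subject_parameters(cfg, i))
  names(sp) <- subjects
  trajs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    generate_sample(templates[[g$label]], sp[[g$subject_id]], cfg,
                    derive_seed(cfg$seed, "sample", g$subject_id, g$label,
                                g$trial_index))
  })
  bundle(tibble(trajectory = trajs, label = grid$label,
                subject_id = grid$subject_id, trial_index = grid$trial_index,
                provenance = "raw"),
         class_set = sort(labels),
         name = sprintf("synthetic-%s-%ds-%dt", cfg$patterns, cfg$n_subjects,
                        cfg$trials_per_pattern))
}
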