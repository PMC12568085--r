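#' Configuration for segmental scaling distortion
#'
#' The distortion augmentation draws fresh per-axis scaling factors
#' `(s_x, s_y) ~ N(mean, variance)` at every segment boundary (multiples of
#' the gap `g`) and multiplies them into all points from that boundary
#' onward, so factors compound along the trajectory. Two presets are used in
#' practice: distortion I (`mean = 1.0, variance = 0.1`) and distortion II
#' (`mean = 1.01, variance = 0.01`).
#'
#' @param mean Mean of the scaling-factor distribution (dimensionless).
#' @param variance Variance of the scaling-factor distribution (>= 0).
#' @param gap Segment gap g in samples (>= 1).
#' @param seed Optional integer seed making the draw deterministic.
#' @param mode `"compound"` applies each boundary's factors to every later
#'   point (factors accumulate); `"per_segment"` applies them only within
#'   the boundary's own segment.
#' @return A list of class `eyw_distortion_config`.
#' @export
distortion_config <- function(mean = 1.0, variance = 0.1, gap = 32, seed = NULL,
                              mode = c("compound", "per_segment")) {
  if (variance < 0) abort("`variance` must be >= 0.")
  if (gap < 1) abort("`gap` must be >= 1.")
  structure(list(mean = mean, variance = variance, gap = as.integer(gap),
                 seed = seed, mode = match.arg(mode)),
            class = "eyw_distortion_config")
}

#' Configuration for window-warping augmentation
#'
#' @param window_ratio Fraction r in (0, 1] of the sequence to warp.
#' @param scale_choices Positive time-scaling factors; one is drawn uniformly
#'   per call (defaults 0.25 and 4.0 — slow down or speed up the window).
#' @param seed Optional integer seed.
#' @return A list of class `eyw_warp_config`.
#' @export
warp_config <- function(window_ratio = 0.3, scale_choices = c(0.25, 4.0),
                        seed = NULL) {
  if (!(window_ratio > 0 && window_ratio <= 1)) {
    abort("`window_ratio` must lie in (0, 1].")
  }
  if (any(scale_choices <= 0)) abort("all `scale_choices` must be > 0.")
  structure(list(window_ratio = window_ratio, scale_choices = scale_choices,
                 seed = seed),
            class = "eyw_warp_config")
}

#' Segmental stochastic scaling distortion
#'
#' Simulates variation in writing speed and amplitude by multiplying random
#' per-axis scaling factors into the trajectory at regular intervals; see
#' [distortion_config()]. Negative draws are clipped to 0.01 — a negative
#' scale would mirror the trajectory, which controlled distortion excludes.
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y` (N >= 1).
#' @param cfg An [distortion_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @param factors Optional matrix (n_boundaries x 2) of scaling factors to
#'   use instead of random draws (for reproducing a specific distortion).
#' @return A distorted trajectory of the same length.
#' @export
distort <- function(traj, cfg, seed = cfg$seed, factors = NULL) {
  stopifnot(inherits(cfg, "eyw_distortion_config"))
  traj <- as_trajectory(traj)
  n <- nrow(traj)
  boundaries <- seq.int(0L, n - 1L, by = cfg$gap)  # i = 0, g, 2g, ... < N
  nb <- length(boundaries)
  if (is.null(factors)) {
    if (!is.null(seed)) set.seed(seed)
    factors <- matrix(rnorm(2 * nb, cfg$mean, sqrt(cfg$variance)), nb, 2)
  }
  if (!is.matrix(factors) || nrow(factors) != nb || ncol(factors) != 2) {
    abort(sprintf("`factors` must be a %d x 2 matrix (one row per boundary).", nb))
  }
  factors[factors < 0.01] <- 0.01
  m <- traj_matrix(traj)
  # scale[j] for point j is the product of factors at boundaries <= j
  seg <- findInterval(0:(n - 1L), boundaries)  # segment index, 1-based
  for (ch in 1:2) {
    cum <- cumprod(factors[, ch])
    if (cfg$mode == "compound") {
      m[, ch] <- m[, ch] * cum[seg]
    } else {
      m[, ch] <- m[, ch] * factors[seg, ch]
    }
  }
  traj_replace(traj, m)
}

#' Window-warping augmentation
#'
#' Selects a random contiguous window of `ceil(N * r)` samples, linearly
#' interpolates it to `ceil(N * r * s)` samples with `s` drawn from
#' `scale_choices` (simulating a locally slower or faster stroke),
#' concatenates it with the untouched flanks, and linearly rescales the
#' whole sequence back to the original length N.
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y` (N >= 4).
#' @param cfg An [warp_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @param .window_start,.scale Optional overrides of the random window start
#'   (1-based) and scale factor, for reproducing a specific warp.
#' @return A warped trajectory of the same length N.
#' @export
window_warp <- function(traj, cfg, seed = cfg$seed,
                        .window_start = NULL, .scale = NULL) {
  stopifnot(inherits(cfg, "eyw_warp_config"))
  traj <- as_trajectory(traj)
  n <- nrow(traj)
  if (n < 4) abort("window warping needs at least 4 samples.")
  if (!is.null(seed)) set.seed(seed)
  w <- ceiling(n * cfg$window_ratio)
  start <- .window_start %||% sample.int(n - w + 1L, 1L)
  scales <- cfg$scale_choices
  # discard scale choices that collapse the window below 2 samples
  usable <- scales[ceiling(n * cfg$window_ratio * scales) >= 2]
  if (length(usable) == 0) {
    abort("every scale choice collapses the warped window below 2 samples.")
  }
  s <- .scale %||% usable[sample.int(length(usable), 1L)]
  wlen <- ceiling(n * cfg$window_ratio * s)
  m <- traj_matrix(traj)
  win <- m[start:(start + w - 1L), , drop = FALSE]
  warped <- apply(win, 2, function(v) {
    approx(seq_len(w), v, xout = seq(1, w, length.out = wlen))$y
  })
  pieced <- rbind(if (start > 1) m[1:(start - 1L), , drop = FALSE],
                  warped,
                  if (start + w - 1L < n) m[(start + w):n, , drop = FALSE])
  np <- nrow(pieced)
  out <- apply(pieced, 2, function(v) {
    approx(seq_len(np), v, xout = seq(1, np, length.out = n))$y
  })
  res <- traj_replace(traj, out)
  res
}

#' Expand a training fold with augmented copies
#'
#' Returns the original samples plus, per original, one distortion-I copy,
#' one distortion-II copy and one window-warp copy (4x the input size).
#' Augmented copies inherit their source's label, subject and trial index
#' and are marked `provenance = "augmented"`, which structurally prevents
#' them from ever entering a test fold. Per-sample random streams are
#' derived from the master seed by hashing (subject, label, trial,
#' technique), so the result is order-independent and reproducible.
#'
#' @param train A sample tibble with `provenance == "raw"` throughout.
#' @param distortion1,distortion2 [distortion_config()]s for the two
#'   distortion presets.
#' @param warp An [warp_config()].
#' @param seed Master integer seed.
#' @return A sample tibble with `4 * nrow(train)` rows.
#' @export
augment_training_set <- function(train,
                                 distortion1 = distortion_config(1.0, 0.1, 32),
                                 distortion2 = distortion_config(1.01, 0.01, 32),
                                 warp = warp_config(),
                                 seed = 1L) {
  if (any(train$provenance != "raw")) {
    abort("augmented samples must not be augmented again.")
  }
  one_technique <- function(technique, fn) {
    out <- train
    out$trajectory <- lapply(seq_len(nrow(train)), function(i) {
      s <- derive_seed(seed, train$subject_id[i], train$label[i],
                       train$trial_index[i], technique)
      fn(train$trajectory[[i]], s)
    })
    out$provenance <- "augmented"
    out
  }
  aug <- list(
    one_technique("distortion1", function(tr, s) distort(tr, distortion1, seed = s)),
    one_technique("distortion2", function(tr, s) distort(tr, distortion2, seed = s)),
    one_technique("warp", function(tr, s) window_warp(tr, warp, seed = s)))
  dplyr::bind_rows(c(list(train), aug))
}
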