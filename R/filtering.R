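#' Configuration for the EOG signal-conditioning chain
#'
#' Describes the three-stage per-channel filter chain applied to EOG-style
#' recordings before length normalization: a median filter against sporadic
#' spikes, a zero-phase low-pass Butterworth filter against high-frequency
#' noise, and a first-order DC blocker that removes constant offsets. Each
#' stage can be disabled; disabling all three reproduces the webcam-style
#' path, where no filtering is applied.
#'
#' @param median_window Odd window length in samples for the median filter.
#' @param lowpass_order Butterworth filter order (>= 1).
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the Nyquist rate.
#' @param sampling_rate_hz Sampling rate of the signal in Hz.
#' @param dc_pole Pole of the DC-blocking recursion, in (0, 1); values close
#'   to 1 remove offsets slowly but distort slow strokes less.
#' @param enabled Logical vector naming the enabled stages, recycled to
#'   length 3 (`median`, `lowpass`, `dc`). `filter_config(enabled = FALSE)`
#'   disables all stages.
#' @return A list of class `eyw_filter_config`.
#' @export
filter_config <- function(median_window = 5, lowpass_order = 5, cutoff_hz = 10,
                          sampling_rate_hz = 125, dc_pole = 0.995,
                          enabled = TRUE) {
  if (median_window < 1 || median_window %% 2 == 0) {
    abort("`median_window` must be odd and >= 1.")
  }
  if (lowpass_order < 1) abort("`lowpass_order` must be >= 1.")
  if (!(cutoff_hz > 0 && cutoff_hz < sampling_rate_hz / 2)) {
    abort("`cutoff_hz` must lie in (0, sampling_rate_hz / 2).")
  }
  if (!(dc_pole > 0 && dc_pole < 1)) abort("`dc_pole` must lie in (0, 1).")
  enabled <- rep_len(as.logical(enabled), 3)
  structure(list(median_window = as.integer(median_window),
                 lowpass_order = as.integer(lowpass_order),
                 cutoff_hz = cutoff_hz, sampling_rate_hz = sampling_rate_hz,
                 dc_pole = dc_pole,
                 enabled = setNames(enabled, c("median", "lowpass", "dc"))),
            class = "eyw_filter_config")
}

#' Sliding median filter with replicate-edge padding
#'
#' `out[i]` is the median of the window centred at `i`, with the first and
#' last samples replicated beyond the edges so the output length equals the
#' input length. Removes isolated 1-2 sample spikes without rounding stroke
#' corners.
#'
#' @param signal Numeric vector.
#' @param window Odd window length, at most `length(signal)`.
#' @return Filtered vector of the same length.
#' @export
median_filter <- function(signal, window) {
  if (window %% 2 == 0 || window < 1) abort("`window` must be odd and >= 1.")
  n <- length(signal)
  if (window > n) abort("`window` must not exceed the signal length.")
  if (window == 1) return(signal)
  h <- (window - 1L) %/% 2L
  padded <- c(rep(signal[1], h), signal, rep(signal[n], h))
  vapply(seq_len(n), function(i) median(padded[i:(i + window - 1L)]), numeric(1))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of the configured
#' order and cutoff. The two passes preserve trajectory geometry (no phase
#' lag) at the cost of doubling the attenuation: the amplitude gain at the
#' cutoff is 0.5 rather than the single-pass 1/sqrt(2).
#'
#' @param signal Numeric vector; must be longer than `3 * lowpass_order`.
#' @param cfg An [filter_config()].
#' @return Filtered vector of the same length.
#' @export
lowpass_filter <- function(signal, cfg) {
  stopifnot(inherits(cfg, "eyw_filter_config"))
  if (length(signal) <= 3 * cfg$lowpass_order) {
    abort(sprintf("signal too short for zero-phase filtering: need > %d samples.",
                  3 * cfg$lowpass_order))
  }
  bt <- signal::butter(cfg$lowpass_order,
                       W = cfg$cutoff_hz / (cfg$sampling_rate_hz / 2),
                       type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass; the pad is long enough for the filter to settle
  n <- length(signal)
  pad <- min(n - 1L, 120L)
  front <- 2 * signal[1] - signal[(pad + 1L):2]
  back <- 2 * signal[n] - signal[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bt, c(front, signal, back)))
  y[(pad + 1L):(pad + n)]
}

#' First-order DC-blocking filter
#'
#' Streaming recursion `y[n] = x[n] - x[n-1] + pole * y[n-1]` with the
#' convention `x[-1] = x[0]` (so `y[0] = 0`). Constant offsets decay
#' geometrically with rate `pole`.
#'
#' @param signal Numeric vector.
#' @param pole Real pole in (0, 1).
#' @return Filtered vector of the same length.
#' @export
dc_block <- function(signal, pole) {
  if (!(pole > 0 && pole < 1)) abort("`pole` must lie in (0, 1).")
  d <- c(0, diff(signal))
  as.numeric(stats::filter(d, pole, method = "recursive"))
}

#' Apply the filter chain to a trajectory
#'
#' Applies the enabled stages in order median -> low-pass -> DC block,
#' independently to the x and y channels. With all stages disabled this is
#' exactly the identity map (the webcam-style path).
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y` columns.
#' @param cfg An [filter_config()].
#' @return A trajectory of the same length.
#' @export
apply_filter_chain <- function(traj, cfg) {
  stopifnot(inherits(cfg, "eyw_filter_config"))
  traj <- as_trajectory(traj)
  if (!any(cfg$enabled)) return(traj)
  m <- traj_matrix(traj)
  for (ch in 1:2) {
    v <- m[, ch]
    if (cfg$enabled[["median"]]) v <- median_filter(v, cfg$median_window)
    if (cfg$enabled[["lowpass"]]) v <- lowpass_filter(v, cfg)
    if (cfg$enabled[["dc"]]) v <- dc_block(v, cfg$dc_pole)
    m[, ch] <- v
  }
  traj_replace(traj, m)
}
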