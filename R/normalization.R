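#' Configuration for trajectory length normalization
#'
#' Houses the target length M of the Fourier-domain length normalization,
#' the amplitude convention, the optional fixed-length zero-padding baseline,
#' and the initial-point normalization switch.
#'
#' @param target_length Target length M (>= 2) of the normalized trajectory.
#' @param amplitude_mode `"preserve"` rescales by M/L so a constant channel
#'   of value c maps to the constant c for any input length L; `"literal"`
#'   keeps the plain 1/M inverse-transform convention, under which amplitude
#'   scales with L/M.
#' @param baseline_pad_length When set, trajectories are zero-padded in the
#'   time domain to this fixed length instead of Fourier-resampled (the
#'   naive fixed-length baseline used for ablation).
#' @param apply_initial_point Whether [preprocess_trajectory()] shifts each
#'   trajectory so its first point is the origin.
#' @param truncation_convention `"lowpass"` (default) keeps the M
#'   lowest-frequency bins of the unshifted spectrum; `"centered_literal"`
#'   applies the centered mod-L block selection, which is only a low-pass
#'   when the spectrum is in zero-centered order.
#' @return A list of class `eyw_norm_config`.
#' @export
normalization_config <- function(target_length = 64,
                                 amplitude_mode = c("preserve", "literal"),
                                 baseline_pad_length = NULL,
                                 apply_initial_point = TRUE,
                                 truncation_convention = c("lowpass", "centered_literal")) {
  if (target_length < 2) abort("`target_length` must be >= 2.")
  if (!is.null(baseline_pad_length) && baseline_pad_length < 1) {
    abort("`baseline_pad_length` must be >= 1 when set.")
  }
  structure(list(target_length = as.integer(target_length),
                 amplitude_mode = match.arg(amplitude_mode),
                 baseline_pad_length = if (is.null(baseline_pad_length)) NULL
                                       else as.integer(baseline_pad_length),
                 apply_initial_point = isTRUE(apply_initial_point),
                 truncation_convention = match.arg(truncation_convention)),
            class = "eyw_norm_config")
}

#' Discrete Fourier transform of a real sequence
#'
#' `X(k) = sum_n x(n) exp(-2i pi k n / L)` for `k = 0, ..., L-1`. For real
#' input the spectrum is Hermitian-symmetric: `X(L-k) = Conj(X(k))`.
#'
#' @param signal Numeric vector of length L >= 1.
#' @return Complex vector of length L.
#' @export
dft <- function(signal) {
  if (length(signal) < 1) abort("`signal` must be non-empty.")
  fft(signal)
}

#' Truncate a spectrum to M bins
#'
#' Keeps the M lowest-frequency bins of a length-L spectrum in standard DFT
#' order: `Xd(k) = X(k)` for `0 <= k < ceil(M/2)` and `Xd(k) = X(k + L - M)`
#' for `ceil(M/2) <= k < M`. This is the exact inverse of the bin placement
#' of [pad_spectrum()]. The `"centered_literal"` convention instead selects
#' the centered block `Xd(k) = X((k + ceil((L-M)/2)) mod L)`.
#'
#' @param X Complex spectrum of length L.
#' @param M Target number of bins, `1 <= M < L`.
#' @param convention See [normalization_config()].
#' @return Complex vector of length M.
#' @export
truncate_spectrum <- function(X, M, convention = c("lowpass", "centered_literal")) {
  convention <- match.arg(convention)
  L <- length(X)
  if (M < 1) abort("`M` must be >= 1.")
  if (M >= L) abort("`M` must be < length(X); use pad_spectrum() to extend.")
  if (convention == "lowpass") {
    khalf <- ceiling(M / 2)
    idx0 <- c(seq_len(khalf) - 1L,             # k = 0, ..., ceil(M/2)-1
              (khalf:(M - 1L)) + L - M)        # k + L - M
    X[idx0 + 1L]
  } else {
    k <- 0:(M - 1L)
    X[((k + ceiling((L - M) / 2)) %% L) + 1L]
  }
}

#' Zero-pad a spectrum to M bins
#'
#' Inserts zeros symmetrically in the middle (highest frequencies) of a
#' length-L spectrum: `Xd(k) = X(k)` for `0 <= k < ceil(L/2)`, zero for
#' `ceil(L/2) <= k < M - floor(L/2)`, and `Xd(k) = X(k - (M - L))` for
#' `M - floor(L/2) <= k < M`.
#'
#' @param X Complex spectrum of length L >= 1.
#' @param M Target number of bins, M > L.
#' @return Complex vector of length M.
#' @export
pad_spectrum <- function(X, M) {
  L <- length(X)
  if (M <= L) abort("`M` must be > length(X); use truncate_spectrum() to shorten.")
  out <- complex(M)
  lo <- ceiling(L / 2)
  hi <- floor(L / 2)
  if (lo > 0) out[seq_len(lo)] <- X[seq_len(lo)]
  if (hi > 0) {
    k <- (M - hi):(M - 1L)
    out[k + 1L] <- X[k - (M - L) + 1L]
  }
  out
}

#' Fourier-domain length normalization
#'
#' Resamples each channel of a variable-length trajectory to a fixed length
#' M by taking the forward DFT, truncating or zero-padding the spectrum to M
#' bins, and inverse-transforming (real part). Because only the lowest
#' frequencies are retained under truncation, the operation doubles as a
#' noise/outlier-suppressing low-pass. With `amplitude_mode = "preserve"`
#' the output is rescaled by M/L so amplitudes do not depend on the input
#' length; `M = L` returns the input unchanged.
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y` (length L >= 2).
#' @param cfg An [normalization_config()].
#' @return A trajectory of exactly `cfg$target_length` points.
#' @export
normalize_length <- function(traj, cfg) {
  stopifnot(inherits(cfg, "eyw_norm_config"))
  traj <- as_trajectory(traj)
  L <- nrow(traj)
  if (L < 2) abort("length normalization needs at least 2 samples.")
  M <- cfg$target_length
  if (M == L) return(traj)
  m <- traj_matrix(traj)
  out <- matrix(0, M, 2)
  for (ch in 1:2) {
    X <- dft(m[, ch])
    Xd <- if (M < L) truncate_spectrum(X, M, cfg$truncation_convention)
          else pad_spectrum(X, M)
    xd <- Re(fft(Xd, inverse = TRUE)) / M
    if (cfg$amplitude_mode == "preserve") xd <- xd * (M / L)
    out[, ch] <- xd
  }
  traj_replace(traj, out, keep_time = FALSE)
}

#' Initial-point normalization
#'
#' Translates a trajectory so its first point is the origin:
#' `p'_i = (x_i - x_0, y_i - y_0)`. Removes absolute-position variability
#' across users and trials while preserving every displacement vector.
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y`.
#' @return A trajectory whose first point is exactly (0, 0).
#' @export
initial_point_normalize <- function(traj) {
  traj <- as_trajectory(traj)
  m <- traj_matrix(traj)
  m[, 1] <- m[, 1] - m[1, 1]
  m[, 2] <- m[, 2] - m[1, 2]
  traj_replace(traj, m)
}

#' Fixed-length zero-padding baseline
#'
#' Appends (0, 0) points until the trajectory reaches `pad_length`. Used as
#' the naive fixed-length baseline against which Fourier-domain length
#' normalization is ablated; inputs longer than `pad_length` are an error
#' (padding is defined without truncation).
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y`.
#' @param pad_length Target length, >= the trajectory length.
#' @return A trajectory of exactly `pad_length` points.
#' @export
zero_pad_baseline <- function(traj, pad_length) {
  traj <- as_trajectory(traj)
  n <- nrow(traj)
  if (n > pad_length) {
    abort(sprintf("trajectory (%d samples) exceeds pad_length (%d); padding is defined without truncation.",
                  n, pad_length))
  }
  if (n == pad_length) return(traj)
  m <- rbind(traj_matrix(traj), matrix(0, pad_length - n, 2))
  traj_replace(traj, m, keep_time = FALSE)
}

#' Full preprocessing of a single trajectory
#'
#' Applies, in order: the filter chain, then either Fourier-domain length
#' normalization followed (optionally) by initial-point normalization, or —
#' when `norm_cfg$baseline_pad_length` is set — the zero-padding baseline
#' (no Fourier resampling, no initial-point shift).
#'
#' @param traj An `eyw_traj` or data frame with `x`, `y`.
#' @param filter_cfg An [filter_config()].
#' @param norm_cfg An [normalization_config()].
#' @return The preprocessed trajectory.
#' @export
preprocess_trajectory <- function(traj, filter_cfg, norm_cfg) {
  out <- apply_filter_chain(traj, filter_cfg)
  if (!is.null(norm_cfg$baseline_pad_length)) {
    return(zero_pad_baseline(out, norm_cfg$baseline_pad_length))
  }
  out <- normalize_length(out, norm_cfg)
  if (norm_cfg$apply_initial_point) out <- initial_point_normalize(out)
  out
}

#' Preprocess every sample of a sample table
#'
#' Maps [preprocess_trajectory()] over the `trajectory` list-column, leaving
#' labels, subject ids and provenance untouched.
#'
#' @param samples A sample tibble (e.g. an `eyw_bundle` or a LOSO fold).
#' @inheritParams preprocess_trajectory
#' @return The same table with preprocessed trajectories.
#' @export
preprocess_samples <- function(samples, filter_cfg, norm_cfg) {
  samples$trajectory <- lapply(samples$trajectory, preprocess_trajectory,
                               filter_cfg = filter_cfg, norm_cfg = norm_cfg)
  samples
}
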