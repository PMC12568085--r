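#' Construct an eye-writing trajectory
#'
#' A trajectory is an ordered sequence of two-dimensional gaze (or EOG-derived)
#' positions, stored as a tibble with columns `x` and `y` and, optionally, a
#' time column `t` in seconds. The sampling rate (Hz), when known, is carried
#' as the `sampling_rate` attribute.
#'
#' @param x,y Numeric coordinate vectors of equal length (N >= 1, all finite).
#' @param t Optional numeric vector of timestamps in seconds.
#' @param sampling_rate Optional sampling rate in Hz (> 0).
#' @return A tibble of class `eyw_traj` with columns (`t`,) `x`, `y`.
#' @examples
#' trajectory(x = c(0, 1, 1), y = c(0, 0, 1))
#' @export
trajectory <- function(x, y, t = NULL, sampling_rate = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 1L) abort("a trajectory needs at least one point.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("all trajectory coordinates must be finite.")
  }
  if (!is.null(t)) {
    t <- as.numeric(t)
    if (length(t) != length(x)) abort("`t` must match the coordinate length.")
    df <- tibble(t = t, x = x, y = y)
  } else {
    df <- tibble(x = x, y = y)
  }
  if (!is.null(sampling_rate)) {
    sampling_rate <- as.numeric(sampling_rate)
    if (!is.finite(sampling_rate) || sampling_rate <= 0) {
      abort("`sampling_rate` must be a positive number.")
    }
  }
  new_trajectory(df, sampling_rate)
}

new_trajectory <- function(df, sampling_rate = NULL) {
  structure(df,
    sampling_rate = sampling_rate,
    class = c("eyw_traj", class(tibble())))
}

#' Coerce a data frame to a trajectory
#'
#' @param df A data frame with numeric columns `x` and `y` (optionally `t`).
#' @inheritParams trajectory
#' @return An `eyw_traj` tibble.
#' @export
as_trajectory <- function(df, sampling_rate = NULL) {
  if (!all(c("x", "y") %in% names(df))) {
    abort("`df` must have columns `x` and `y`.")
  }
  trajectory(df$x, df$y, t = if ("t" %in% names(df)) df$t else NULL,
             sampling_rate = sampling_rate %||% attr(df, "sampling_rate"))
}

#' Number of points in a trajectory
#' @param traj A trajectory (or any data frame with an `x` column).
#' @return Integer length N.
#' @export
traj_length <- function(traj) nrow(traj)

#' Sampling rate of a trajectory
#' @param traj A trajectory.
#' @return Sampling rate in Hz, or `NULL` when unknown.
#' @export
sampling_rate <- function(traj) attr(traj, "sampling_rate")

traj_matrix <- function(traj) cbind(x = traj$x, y = traj$y)

# Rebuild a trajectory from a coordinate matrix, preserving metadata unless
# the length changed (then timestamps no longer apply).
traj_replace <- function(traj, m, keep_time = TRUE) {
  n <- nrow(m)
  keep_time <- keep_time && n == nrow(traj) && "t" %in% names(traj)
  trajectory(m[, 1], m[, 2],
    t = if (keep_time) traj$t else NULL,
    sampling_rate = if (n == nrow(traj)) sampling_rate(traj) else NULL)
}

#' Read a trajectory from CSV
#'
#' The on-disk dialect is a comma-separated UTF-8 file with a header naming
#' columns `x` and `y` and, optionally, `t` (seconds). When a `t` column with
#' uniform spacing is present the sampling rate is inferred as `1 / spacing`.
#'
#' @param path Path to an existing CSV file.
#' @return An `eyw_traj` tibble.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(paste0("cannot parse ", path, ": ", conditionMessage(e))))
  if (nrow(df) == 0L) abort(paste0("empty trajectory file: ", path))
  missing <- setdiff(c("x", "y"), names(df))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in intersect(c("t", "x", "y"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(paste0(path, ": non-numeric value in column `", col, "` at data row ",
                   if (is.na(bad)) "?" else bad))
    }
    if (anyNA(v)) {
      abort(paste0(path, ": missing value in column `", col, "` at data row ",
                   which(is.na(v))[1]))
    }
  }
  rate <- NULL
  if ("t" %in% names(df) && nrow(df) >= 2) {
    dt <- diff(df$t)
    if (all(dt > 0) && diff(range(dt)) <= 1e-9 * max(abs(dt))) {
      rate <- 1 / mean(dt)
    }
  }
  trajectory(df$x, df$y, t = if ("t" %in% names(df)) df$t else NULL,
             sampling_rate = rate)
}

#' Write a trajectory to CSV
#'
#' Inverse of [read_trajectory_csv()]; coordinates are written with 17
#' significant digits so a round trip preserves them to double precision.
#'
#' @param traj An `eyw_traj` (or data frame with `x`, `y`).
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!dir.exists(dirname(path))) {
    abort(paste0("directory does not exist: ", dirname(path)))
  }
  cols <- intersect(c("t", "x", "y"), names(traj))
  lines <- c(paste(cols, collapse = ","),
             do.call(paste, c(lapply(cols, function(cl) sprintf("%.17g", traj[[cl]])),
                              sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.eyw_traj <- function(x, ...) {
  rate <- attr(x, "sampling_rate")
  cat(sprintf("# eye-writing trajectory: %d points%s\n", nrow(x),
              if (is.null(rate)) "" else sprintf(" @ %g Hz", rate)))
  NextMethod()
}

#' Plot a trajectory as a 2-D path
#'
#' @param object An `eyw_traj`.
#' @param ... Unused.
#' @return A ggplot object; the first point is marked.
#' @method autoplot eyw_traj
#' @export
autoplot.eyw_traj <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(data = df[1, ], colour = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Eye-writing trajectory",
                  subtitle = sprintf("%d samples; red dot marks the start", nrow(df)))
}

#' @importFrom rlang .data
NULL
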