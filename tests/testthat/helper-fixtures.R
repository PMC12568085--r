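# Shared fixtures built in code.

# a smooth two-channel trajectory resembling an eye-written stroke
smooth_traj <- function(n = 200, seed = 1) {
  set.seed(seed)
  tt <- seq(0, 2 * pi, length.out = n)
  trajectory(0.5 + 0.3 * cos(tt) + cumsum(rnorm(n, 0, 1e-3)),
             0.5 + 0.3 * sin(2 * tt) + cumsum(rnorm(n, 0, 1e-3)))
}

# tiny bundle written to disk as trajectory CSVs plus a manifest
write_tiny_manifest <- function(dir, n_subjects = 2, labels = c("0", "1"),
                                trials = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- character(0)
  for (s in seq_len(n_subjects)) {
    for (lb in labels) {
      for (tr in seq_len(trials) - 1L) {
        f <- sprintf("s%d_%s_%d.csv", s, lb, tr)
        write_trajectory_csv(smooth_traj(50, seed = s * 100 + tr), file.path(dir, f))
        rows <- c(rows, sprintf("%s,%s,S%d,%d", f, lb, s, tr))
      }
    }
  }
  mf <- file.path(dir, "manifest.csv")
  writeLines(c("file,label,subject_id,trial_index", rows), mf)
  mf
}

desk_generator <- function(n_subjects = 4, trials = 2, seed = 42) {
  generator_config(n_subjects = n_subjects, trials_per_pattern = trials,
                   seed = seed)
}
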