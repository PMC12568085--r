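test_that("distortion with zero variance and unit mean is the identity", {
  tr <- smooth_traj(100, seed = 1)
  for (g in c(1, 7, 32)) {
    out <- distort(tr, distortion_config(mean = 1, variance = 0, gap = g), seed = 5)
    expect_equal(out$x, tr$x, tolerance = 1e-12)
    expect_equal(out$y, tr$y, tolerance = 1e-12)
  }
})

test_that("distortion compounds stubbed factors across segment boundaries", {
  tr <- trajectory(rep(1, 4), rep(1, 4))
  cfg <- distortion_config(gap = 2)
  out <- distort(tr, cfg, factors = rbind(c(2, 1), c(3, 1)))
  expect_equal(out$x, c(2, 2, 6, 6))
  expect_equal(out$y, rep(1, 4))

  # per-segment mode applies each factor only within its own segment
  cfg_seg <- distortion_config(gap = 2, mode = "per_segment")
  out_seg <- distort(tr, cfg_seg, factors = rbind(c(2, 1), c(3, 1)))
  expect_equal(out_seg$x, c(2, 2, 3, 3))
})

test_that("distortion is deterministic under a seed and varies across seeds", {
  tr <- smooth_traj(120, seed = 3)
  cfg <- distortion_config(1.0, 0.1, 32)
  a <- distort(tr, cfg, seed = 11)
  b <- distort(tr, cfg, seed = 11)
  c <- distort(tr, cfg, seed = 12)
  expect_identical(a$x, b$x)
  expect_false(isTRUE(all.equal(a$x, c$x)))
  expect_equal(nrow(a), nrow(tr))
})

test_that("window warping preserves length and reduces to identity at s = 1", {
  tr <- smooth_traj(150, seed = 4)
  cfg1 <- warp_config(window_ratio = 0.3, scale_choices = 1.0)
  out1 <- window_warp(tr, cfg1, seed = 2)
  expect_equal(out1$x, tr$x, tolerance = 1e-9)
  expect_equal(out1$y, tr$y, tolerance = 1e-9)

  cfg <- warp_config(0.3, c(0.25, 4.0))
  for (seed in 1:5) {
    out <- window_warp(tr, cfg, seed = seed)
    expect_equal(nrow(out), nrow(tr))
    expect_true(all(is.finite(out$x)))
  }
  expect_error(window_warp(trajectory(1:3, 1:3), cfg), "at least 4")
})

test_that("window warping matches an explicit piecewise-linear oracle", {
  # linear ramp, fixed window [10, 25) of N = 50, scale 4
  n <- 50
  tr <- trajectory(0:(n - 1), rep(0, n))
  cfg <- warp_config(window_ratio = 0.3, scale_choices = c(0.25, 4))
  out <- window_warp(tr, cfg, .window_start = 10, .scale = 4)

  w <- ceiling(n * 0.3)                     # 15 window samples: indices 10..24
  wlen <- ceiling(n * 0.3 * 4)              # stretched to 60
  win <- tr$x[10:24]
  warped <- approx(seq_len(w), win, xout = seq(1, w, length.out = wlen))$y
  pieced <- c(tr$x[1:9], warped, tr$x[25:n])
  oracle <- approx(seq_along(pieced), pieced,
                   xout = seq(1, length(pieced), length.out = n))$y
  expect_equal(out$x, oracle, tolerance = 1e-8)
})

test_that("augmentation expands a fold 4x with inherited metadata", {
  b <- generate_dataset(desk_generator(n_subjects = 3, trials = 1))
  train <- b[b$subject_id != "S01", ]
  aug <- augment_training_set(train, seed = 7)
  expect_equal(nrow(aug), 4 * nrow(train))
  expect_equal(sum(aug$provenance == "augmented"), 3 * nrow(train))
  expect_equal(sum(aug$provenance == "raw"), nrow(train))

  # augmented copies keep their source's label/subject/trial and length
  for (i in seq_len(nrow(train))) {
    copies <- aug[aug$provenance == "augmented" &
                  aug$subject_id == train$subject_id[i] &
                  aug$label == train$label[i] &
                  aug$trial_index == train$trial_index[i], ]
    expect_equal(nrow(copies), 3)
    expect_true(all(vapply(copies$trajectory, nrow, numeric(1)) ==
                    nrow(train$trajectory[[i]])))
  }

  # determinism under the master seed
  aug2 <- augment_training_set(train, seed = 7)
  expect_equal(lapply(aug$trajectory, as.data.frame),
               lapply(aug2$trajectory, as.data.frame))

  # no double augmentation
  expect_error(augment_training_set(aug, seed = 7), "not be augmented again")
})

test_that("distortion converges to the identity as the variance vanishes", {
  tr <- smooth_traj(80, seed = 6)
  errs <- vapply(c(1e-2, 1e-4, 1e-6), function(v) {
    out <- distort(tr, distortion_config(1, v, 16), seed = 3)
    max(abs(out$x - tr$x), abs(out$y - tr$y))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-2)
})
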