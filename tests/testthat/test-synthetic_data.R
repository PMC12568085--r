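test_that("built-in templates are well-formed", {
  d10 <- builtin_templates("digits10")
  k12 <- builtin_templates("katakana12")
  expect_length(d10, 10)
  expect_length(k12, 12)
  expect_equal(anyDuplicated(names(d10)), 0)
  for (tmpl in c(d10, k12)) {
    expect_gte(nrow(tmpl), 2)
    expect_true(all(tmpl >= 0 & tmpl <= 1))                 # unit square
    steps <- diff(tmpl)
    expect_true(all(rowSums(abs(steps)) > 0))               # distinct vertices
  }
})

test_that("generated datasets have the declared balanced design", {
  b950 <- generate_dataset(generator_config(n_subjects = 19,
                                            trials_per_pattern = 5, seed = 1))
  expect_equal(nrow(b950), 950)
  b540 <- generate_dataset(generator_config(n_subjects = 18,
                                            trials_per_pattern = 3, seed = 1))
  expect_equal(nrow(b540), 540)
  b720 <- generate_dataset(generator_config(n_subjects = 6, patterns = "katakana12",
                                            trials_per_pattern = 10, seed = 1))
  expect_equal(nrow(b720), 720)
  expect_length(class_set(b720), 12)

  # every (subject, label) cell holds exactly trials_per_pattern samples
  cells <- table(b950$subject_id, b950$label)
  expect_true(all(cells == 5))
})

test_that("durations, lengths and determinism follow the generator contract", {
  cfg <- desk_generator(n_subjects = 5, trials = 2, seed = 17)
  b <- generate_dataset(cfg)
  lens <- vapply(b$trajectory, nrow, numeric(1))
  durations <- lens / cfg$sampling_rate_hz
  expect_true(all(durations >= 1.69 - 0.5 / 30 & durations <= 23.51 + 0.5 / 30))
  expect_gt(stats::sd(lens), 0)            # lengths vary across samples
  expect_true(any(lens < 64) || any(lens > 64) == TRUE)

  b2 <- generate_dataset(cfg)
  expect_equal(lapply(b$trajectory, as.data.frame),
               lapply(b2$trajectory, as.data.frame))
})

test_that("noiseless identity-subject samples trace the template", {
  cfg <- generator_config(n_subjects = 2, trials_per_pattern = 1,
                          noise_sd = 0, spike_prob = 0,
                          subject_offset_sd = 0, subject_scale_sd = 0, seed = 3)
  tmpl <- builtin_templates("digits10")[["7"]]
  s <- generate_sample(tmpl, list(offset = c(0, 0), scale = c(1, 1)), cfg,
                       stream_seed = 99)
  pts <- cbind(s$x, s$y)
  # every template vertex is hit (to interpolation resolution)
  for (v in seq_len(nrow(tmpl))) {
    d <- sqrt((pts[, 1] - tmpl[v, 1])^2 + (pts[, 2] - tmpl[v, 2])^2)
    expect_lt(min(d), 0.02)
  }
  expect_equal(unname(pts[1, ]), unname(tmpl[1, ]), tolerance = 1e-6)
  expect_equal(unname(pts[nrow(pts), ]), unname(tmpl[nrow(tmpl), ]),
               tolerance = 1e-6)
})

test_that("spike artifacts appear at the configured rate and are removable", {
  cfg <- generator_config(n_subjects = 2, trials_per_pattern = 1,
                          noise_sd = 0.005, spike_prob = 0.02,
                          sampling_rate_hz = 125, seed = 6)
  tmpl <- builtin_templates("digits10")[["0"]]
  s <- generate_sample(tmpl, list(offset = c(0, 0), scale = c(1, 1)), cfg,
                       stream_seed = 12)
  clean <- generate_sample(tmpl, list(offset = c(0, 0), scale = c(1, 1)),
                           generator_config(n_subjects = 2, trials_per_pattern = 1,
                                            noise_sd = 0.005, spike_prob = 0,
                                            sampling_rate_hz = 125, seed = 6),
                           stream_seed = 12)
  # spikes moved some samples far off the glyph; the median filter removes most
  expect_gt(max(abs(s$x - clean$x)), 0.4)
  filtered <- median_filter(s$x, 5)
  expect_lt(mean(abs(filtered - clean$x)), 0.05)
})

test_that("preprocessed synthetic classes are nearest-centroid separable", {
  # a deliberately simple classifier must already exceed 80% LOSO accuracy,
  # so the deep model's target is not vacuous
  b <- generate_dataset(generator_config(n_subjects = 5, trials_per_pattern = 3,
                                         seed = 23))
  pre <- preprocess_samples(b, filter_config(enabled = FALSE),
                            normalization_config(64))
  feats <- t(vapply(pre$trajectory, function(tr) c(tr$x, tr$y), numeric(128)))
  labs <- pre$label
  subj <- pre$subject_id
  correct <- 0
  for (s in unique(subj)) {
    tr_idx <- subj != s
    cls <- sort(unique(labs))
    centroids <- t(vapply(cls, function(cl) {
      colMeans(feats[tr_idx & labs == cl, , drop = FALSE])
    }, numeric(ncol(feats))))
    for (i in which(!tr_idx)) {
      d <- rowSums(sweep(centroids, 2, feats[i, ])^2)
      correct <- correct + (cls[which.min(d)] == labs[i])
    }
  }
  expect_gt(100 * correct / nrow(b), 80)
})
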