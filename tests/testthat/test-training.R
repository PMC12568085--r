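test_that("cross-entropy has its closed-form values", {
  perfect <- diag(10)
  expect_equal(cross_entropy(perfect, diag(10)), 0, tolerance = 1e-9)
  uniform <- matrix(1 / 10, 4, 10)
  labels <- matrix(0, 4, 10); labels[cbind(1:4, c(1, 5, 7, 10))] <- 1
  expect_equal(cross_entropy(uniform, labels), log(10), tolerance = 1e-9)

  # hand-built two-sample case
  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  y <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(cross_entropy(p, y), -(log(0.7) + log(0.6)) / 2, tolerance = 1e-12)

  expect_error(cross_entropy(p, y[, 1:2]), "identical dimensions")
  expect_error(cross_entropy(p * 2, y), "sum to 1")
})

test_that("cosine annealing warm-restarts as scheduled", {
  cfg <- train_config(lr_max = 0.001, lr_min = 0, cosine_period = 16)
  expect_equal(cosine_lr(0, cfg), 0.001)
  expect_equal(cosine_lr(8, cfg), 0.0005, tolerance = 1e-12)   # cos(pi/2) = 0
  expect_equal(cosine_lr(16, cfg), 0.001)                      # warm restart
  cfg2 <- train_config(lr_max = 0.001, lr_min = 1e-6, cosine_period = 16)
  expect_equal(cosine_lr(8, cfg2), (0.001 + 1e-6) / 2, tolerance = 1e-12)

  # a 400-epoch trace restarts ceiling(400 / 16) = 25 times
  trace <- cosine_lr(0:399, cfg)
  expect_equal(sum(trace == 0.001), ceiling(400 / 16))
  expect_true(all(trace >= 0 & trace <= 0.001))
})

test_that("metrics match hand-computed macro averages", {
  cls <- c("a", "b", "c")
  all_right <- compute_metrics(rep(cls, 4), rep(cls, 4), cls)
  expect_equal(unlist(all_right), c(accuracy = 100, precision = 100,
                                    recall = 100, f1 = 100))

  # hand-built 3-class confusion: truths 3/3/3
  truths <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  preds <- c("a", "a", "b", "b", "b", "c", "c", "c", "c")
  got <- compute_metrics(preds, truths, cls)
  prec <- c(2 / 2, 2 / 3, 3 / 4)
  rec <- c(2 / 3, 2 / 3, 3 / 3)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(got$accuracy, 100 * 7 / 9)
  expect_equal(got$precision, 100 * mean(prec))
  expect_equal(got$recall, 100 * mean(rec))
  expect_equal(got$f1, 100 * mean(f1))

  expect_error(compute_metrics(c("a", "z"), c("a", "b"), cls), "class set")
})

test_that("with balanced classes macro recall equals accuracy exactly", {
  set.seed(31)
  cls <- as.character(0:9)
  for (rep in 1:20) {
    truths <- rep(cls, each = 5)
    preds <- ifelse(runif(50) < 0.7, truths, sample(cls, 50, TRUE))
    got <- compute_metrics(preds, truths, cls)
    expect_equal(got$recall, got$accuracy, tolerance = 1e-12)
  }
})

test_that("fold training learns a separable desk-scale problem", {
  b <- generate_dataset(desk_generator(n_subjects = 3, trials = 3, seed = 8))
  sp <- loso_splits(b)
  fr <- train_fold(sp[1, ], model_config(64, 10),
                   train_config(epochs = 40, batch_size = 64, seed = 4),
                   filter_config(enabled = FALSE), normalization_config(64),
                   augment = list(distortion1 = distortion_config(1.0, 0.1, 32),
                                  distortion2 = distortion_config(1.01, 0.01, 32),
                                  warp = warp_config()))
  expect_s3_class(fr, "eyw_fold_result")
  expect_equal(fr$n_test, 30)
  expect_gte(fr$accuracy, 70)          # 10 classes; chance is 10%
  expect_true(fr$loss >= 0)
  # balanced test set: the macro-recall identity holds in the report too
  expect_equal(fr$recall, fr$accuracy)
})

test_that("LOSO reports aggregate their folds consistently", {
  b <- generate_dataset(desk_generator(n_subjects = 3, trials = 2, seed = 9))
  rep <- run_loso(b, model_config(64, 10),
                  train_config(epochs = 8, batch_size = 64, seed = 5),
                  filter_config(enabled = FALSE), normalization_config(64))
  expect_equal(nrow(rep$folds), 3)
  expect_setequal(rep$folds$test_subject, unique(b$subject_id))
  for (m in c("loss", "accuracy", "precision", "recall", "f1")) {
    srow <- rep$summary[rep$summary$metric == m, ]
    expect_equal(srow$mean, mean(rep$folds[[m]]), tolerance = 1e-6)
    expect_equal(srow$std, sqrt(mean((rep$folds[[m]] - mean(rep$folds[[m]]))^2)),
                 tolerance = 1e-6)
  }
  # tidiers
  expect_identical(tidy(rep), rep$folds)
  g <- glance(rep)
  expect_equal(g$accuracy, mean(rep$folds$accuracy))
  expect_equal(g$n_folds, 3)
  expect_s3_class(autoplot(rep), "ggplot")
})
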