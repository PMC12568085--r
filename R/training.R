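#' Training configuration
#'
#' Optimization settings for cross-entropy training with Adam/AMSGrad and a
#' cosine-annealing warm-restart learning-rate schedule. The defaults mirror
#' the common settings used across the reference experiments: 400 epochs,
#' batch size 512, L2 weight decay 0.1, maximum learning rate 0.001 and a
#' 16-iteration annealing period. Scaled-down runs override `epochs` and
#' `batch_size`.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 coefficient added to every parameter gradient.
#' @param amsgrad Use the AMSGrad variant of Adam.
#' @param lr_max,lr_min Maximum/minimum learning rate of the cosine schedule
#'   (`lr_min` may be 0).
#' @param cosine_period Warm-restart period P, in scheduling units.
#' @param schedule_unit `"epoch"` (default; with batch sizes at or above the
#'   fold size an epoch is one iteration) or `"step"`.
#' @param seed Master seed for shuffling, dropout and weight initialization.
#' @return A list of class `eyw_train_config`.
#' @export
train_config <- function(epochs = 400, batch_size = 512, weight_decay = 0.1,
                         amsgrad = TRUE, lr_max = 0.001, lr_min = 0,
                         cosine_period = 16, schedule_unit = c("epoch", "step"),
                         seed = 1L) {
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (cosine_period < 1) abort("`cosine_period` must be >= 1.")
  if (!(lr_min == 0 || (lr_min > 0 && lr_min <= lr_max))) {
    abort("need 0 < lr_min <= lr_max, or lr_min = 0.")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, amsgrad = isTRUE(amsgrad),
                 lr_max = lr_max, lr_min = lr_min,
                 cosine_period = as.integer(cosine_period),
                 schedule_unit = match.arg(schedule_unit),
                 seed = as.integer(seed)),
            class = "eyw_train_config")
}

#' Multi-class cross-entropy loss
#'
#' `L = -(1/N) * sum_i sum_j y_ij log(p_ij)` over N samples and C classes,
#' with predicted probabilities clipped below at 1e-12 before the log.
#'
#' @param probabilities N x C matrix of predicted class probabilities (rows
#'   sum to 1 within 1e-6).
#' @param labels N x C one-hot indicator matrix.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(probabilities, labels) {
  if (!all(dim(probabilities) == dim(labels))) {
    abort("`probabilities` and `labels` must have identical dimensions.")
  }
  if (any(abs(rowSums(probabilities) - 1) > 1e-6)) {
    abort("rows of `probabilities` must sum to 1.")
  }
  p <- pmax(probabilities, 1e-12)
  -sum(labels * log(p)) / nrow(labels)
}

#' Cosine-annealing warm-restart learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi * (t mod P) / P)) / 2`,
#' restarting to `lr_max` every P units.
#'
#' @param iteration Nonnegative scheduling index t (0-based).
#' @param cfg An [train_config()].
#' @return The learning rate at `iteration`.
#' @export
cosine_lr <- function(iteration, cfg) {
  if (any(iteration < 0)) abort("`iteration` must be >= 0.")
  P <- cfg$cosine_period
  cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) *
    (1 + cos(pi * (iteration %% P) / P))
}

#' Classification metrics in percent
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the declared
#' class set. With balanced test classes, macro recall equals accuracy
#' exactly. Classes with no true instances enter the macro averages (with
#' recall 0) only when the classifier predicted them; 0/0 ratios count as 0.
#'
#' @param predictions,truths Equal-length vectors of class labels.
#' @param class_set Ordered character vector of valid classes.
#' @return A named list: `accuracy`, `precision`, `recall`, `f1`, each in
#'   [0, 100].
#' @export
compute_metrics <- function(predictions, truths, class_set) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths) || length(truths) < 1) {
    abort("`predictions` and `truths` must be equal-length and non-empty.")
  }
  if (!all(c(predictions, truths) %in% class_set)) {
    abort("labels outside the declared class set.")
  }
  cm <- table(factor(truths, levels = class_set),
              factor(predictions, levels = class_set))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  active <- support > 0 | predicted > 0
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, predicted)[active]
  rec <- safe_div(tp, support)[active]
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = 100 * sum(tp) / length(truths),
       precision = 100 * mean(prec),
       recall = 100 * mean(rec),
       f1 = 100 * mean(f1))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_step <- function(layers, lr, wd, amsgrad, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in layers) {
    for (p in l$params) {
      w <- get(p, envir = l)
      mn <- paste0(".m_", p)
      if (!exists(mn, envir = l, inherits = FALSE)) {
        assign(mn, numeric(length(w)), envir = l)
        assign(paste0(".v_", p), numeric(length(w)), envir = l)
        assign(paste0(".h_", p), numeric(length(w)), envir = l)
      }
      adam_update_cpp(w, get(paste0("d", p), envir = l),
                      get(mn, envir = l), get(paste0(".v_", p), envir = l),
                      get(paste0(".h_", p), envir = l),
                      lr, wd, beta1, beta2, eps, t, amsgrad)
    }
  }
}

samples_to_array <- function(samples, L) {
  n <- nrow(samples)
  x <- array(0, c(2, L, n))
  for (i in seq_len(n)) {
    tr <- samples$trajectory[[i]]
    if (nrow(tr) != L) {
      abort(sprintf("sample %d has length %d, expected %d; preprocess first.",
                    i, nrow(tr), L))
    }
    x[1, , i] <- tr$x
    x[2, , i] <- tr$y
  }
  x
}

eval_model <- function(model, x, y_idx, class_labels, chunk = 256L) {
  n <- dim(x)[3]
  C <- model$cfg$n_classes
  probs <- matrix(0, n, C)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    logits <- t(model_fw(model, x[, , s:e, drop = FALSE], training = FALSE))
    probs[s:e, ] <- softmax_rows(logits)
  }
  onehot <- matrix(0, n, C)
  onehot[cbind(seq_len(n), y_idx)] <- 1
  preds <- class_labels[max.col(probs, ties.method = "first")]
  list(probs = probs, preds = preds,
       loss = cross_entropy(probs, onehot))
}

#' Train and evaluate one leave-one-subject-out fold
#'
#' Augments the training samples (unless `augment` is `NULL`), preprocesses
#' both portions, trains the model with Adam/AMSGrad minimizing
#' cross-entropy under the cosine warm-restart schedule, and evaluates the
#' final-epoch model on the held-out subject. Augmented samples never reach
#' the test side by construction.
#'
#' @param split One row of [loso_splits()] (or a list with `test_subject`,
#'   `train`, `test`).
#' @param model_cfg An [model_config()].
#' @param train_cfg An [train_config()].
#' @param filter_cfg An [filter_config()].
#' @param norm_cfg An [normalization_config()].
#' @param augment `NULL` for no augmentation, or a list with elements
#'   `distortion1`, `distortion2`, `warp` (configs for
#'   [augment_training_set()]).
#' @param class_labels Ordered class set; defaults to the sorted labels of
#'   the split.
#' @param verbose Emit one structured log line per epoch (subject, epoch,
#'   learning rate, mean training loss).
#' @return A one-row tibble (class `eyw_fold_result`): `test_subject`,
#'   `loss`, `accuracy`, `precision`, `recall`, `f1`, `n_test`.
#' @export
train_fold <- function(split, model_cfg, train_cfg, filter_cfg, norm_cfg,
                       augment = NULL, class_labels = NULL, verbose = FALSE) {
  train <- if (is.data.frame(split$train)) split$train else split$train[[1]]
  test <- if (is.data.frame(split$test)) split$test else split$test[[1]]
  subject <- split$test_subject[[1]]
  if (nrow(train) == 0 || nrow(test) == 0) abort("empty train or test fold.")
  class_labels <- class_labels %||% sort(unique(c(train$label, test$label)))

  if (!is.null(augment)) {
    train <- augment_training_set(train,
      distortion1 = augment$distortion1, distortion2 = augment$distortion2,
      warp = augment$warp,
      seed = derive_seed(train_cfg$seed, subject, "augment"))
  }
  train <- preprocess_samples(train, filter_cfg, norm_cfg)
  test <- preprocess_samples(test, filter_cfg, norm_cfg)

  L <- model_cfg$input_length
  xtr <- samples_to_array(train, L)
  xte <- samples_to_array(test, L)
  ytr <- match(train$label, class_labels)
  yte <- match(test$label, class_labels)
  n <- dim(xtr)[3]
  C <- model_cfg$n_classes

  model <- init_model(model_cfg, seed = derive_seed(train_cfg$seed, subject, "init"))
  layers <- model_layers(model)
  set.seed(derive_seed(train_cfg$seed, subject, "train"))
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    epoch_loss <- 0
    epoch_count <- 0L
    ord <- sample.int(n)
    starts <- seq(1, n, by = train_cfg$batch_size)
    # avoid a trailing singleton batch (batch statistics need >= 2 samples)
    if (length(starts) > 1 && n - starts[length(starts)] == 0L) {
      starts <- starts[-length(starts)]
    }
    for (s in starts) {
      e <- min(s + train_cfg$batch_size - 1L, n)
      idx <- ord[s:e]
      b <- length(idx)
      step <- step + 1L
      unit <- if (train_cfg$schedule_unit == "epoch") epoch - 1L else step - 1L
      lr <- cosine_lr(unit, train_cfg)
      logits <- model_fw(model, xtr[, , idx, drop = FALSE], training = TRUE)
      p <- t(softmax_rows(t(logits)))               # C x b
      onehot <- matrix(0, C, b)
      onehot[cbind(ytr[idx], seq_len(b))] <- 1
      model_bw(model, (p - onehot) / b)
      adam_step(layers, lr, train_cfg$weight_decay, train_cfg$amsgrad, step)
      epoch_loss <- epoch_loss - sum(log(pmax(p[cbind(ytr[idx], seq_len(b))], 1e-12)))
      epoch_count <- epoch_count + b
    }
    if (verbose) {
      message(sprintf("subject %s epoch %d lr %.2e train_loss %.4f",
                      subject, epoch, cosine_lr(epoch - 1L, train_cfg),
                      epoch_loss / epoch_count))
    }
  }

  ev <- eval_model(model, xte, yte, class_labels)
  metrics <- compute_metrics(ev$preds, test$label, class_labels)
  structure(tibble(test_subject = subject, loss = ev$loss,
                   accuracy = metrics$accuracy, precision = metrics$precision,
                   recall = metrics$recall, f1 = metrics$f1,
                   n_test = nrow(test)),
            class = c("eyw_fold_result", class(tibble())))
}

#' Run a full leave-one-subject-out evaluation
#'
#' Trains one model per subject (testing on that subject, training on all
#' others) and aggregates per-fold loss, accuracy and macro
#' precision/recall/F1 into means and standard deviations.
#'
#' @param x An `eyw_bundle` of raw samples.
#' @inheritParams train_fold
#' @param verbose Print one line per finished fold.
#' @return An `eyw_loso_report`: a list with `folds` (tibble), `summary`
#'   (mean/std per metric) and a configuration fingerprint.
#' @export
run_loso <- function(x, model_cfg, train_cfg, filter_cfg, norm_cfg,
                     augment = NULL, verbose = FALSE) {
  splits <- loso_splits(x)
  cls <- class_set(x)
  if (model_cfg$n_classes != length(cls)) {
    abort(sprintf("model_cfg$n_classes (%d) != bundle classes (%d).",
                  model_cfg$n_classes, length(cls)))
  }
  folds <- vector("list", nrow(splits))
  for (i in seq_len(nrow(splits))) {
    folds[[i]] <- train_fold(splits[i, ], model_cfg, train_cfg, filter_cfg,
                             norm_cfg, augment, class_labels = cls)
    if (verbose) {
      message(sprintf("fold %s: accuracy %.2f%%, loss %.4f",
                      folds[[i]]$test_subject, folds[[i]]$accuracy,
                      folds[[i]]$loss))
    }
  }
  folds <- dplyr::bind_rows(folds)
  new_loso_report(folds, fingerprint = config_fingerprint(model_cfg, train_cfg,
                                                          filter_cfg, norm_cfg,
                                                          augment))
}

# population standard deviation, matching the report aggregation contract
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

new_loso_report <- function(folds, fingerprint = NA_character_) {
  metrics <- c("loss", "accuracy", "precision", "recall", "f1")
  summary <- tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1), USE.NAMES = FALSE),
    std = vapply(metrics, function(m) pop_sd(folds[[m]]), numeric(1), USE.NAMES = FALSE))
  structure(list(folds = folds, summary = summary, fingerprint = fingerprint),
            class = "eyw_loso_report")
}

config_fingerprint <- function(...) {
  blob <- paste(utils::capture.output(utils::str(list(...))), collapse = "\n")
  sprintf("%08x", derive_seed(0, blob))
}

#' @export
print.eyw_loso_report <- function(x, ...) {
  cat(sprintf("# LOSO report: %d folds (fingerprint %s)\n",
              nrow(x$folds), x$fingerprint))
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("  mean accuracy %.2f%% (std %.2f)\n", acc$mean, acc$std))
  print(x$folds)
  invisible(x)
}

#' @rdname run_loso
#' @param object,x,... An `eyw_loso_report` (for the tidiers).
#' @method tidy eyw_loso_report
#' @export
tidy.eyw_loso_report <- function(x, ...) x$folds

#' @rdname run_loso
#' @method glance eyw_loso_report
#' @export
glance.eyw_loso_report <- function(x, ...) {
  s <- x$summary
  out <- as.list(c(setNames(s$mean, s$metric),
                   setNames(s$std, paste0(s$metric, "_std"))))
  as_tibble(c(out, n_folds = nrow(x$folds)))
}

#' @rdname run_loso
#' @method autoplot eyw_loso_report
#' @export
autoplot.eyw_loso_report <- function(object, ...) {
  df <- object$folds
  mean_acc <- mean(df$accuracy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test_subject, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean_acc, linetype = "dashed") +
    ggplot2::labs(x = "held-out subject", y = "accuracy (%)",
                  title = "Leave-one-subject-out accuracy",
                  subtitle = sprintf("mean %.2f%%", mean_acc))
}

#' Compare pipeline configurations on the same LOSO folds
#'
#' Runs [run_loso()] for each named configuration and reports per-config
#' mean accuracy plus a two-tailed exact Wilcoxon signed-rank p-value of its
#' per-subject accuracies against the first (baseline) configuration.
#'
#' @param x An `eyw_bundle`.
#' @param configs Named list; each element is a list with `model_cfg`,
#'   `train_cfg`, `filter_cfg`, `norm_cfg` and optionally `augment`.
#' @param verbose Passed through to [run_loso()].
#' @return A tibble with one row per configuration: `config`,
#'   `mean_accuracy`, `std_accuracy`, `p_vs_baseline` (NA for the baseline
#'   itself), plus a `report` list-column.
#' @export
compare_pipelines <- function(x, configs, verbose = FALSE) {
  if (is.null(names(configs)) || any(names(configs) == "")) {
    abort("`configs` must be a fully named list.")
  }
  reports <- lapply(configs, function(cf) {
    run_loso(x, cf$model_cfg, cf$train_cfg, cf$filter_cfg, cf$norm_cfg,
             augment = cf$augment, verbose = verbose)
  })
  base_acc <- reports[[1]]$folds$accuracy
  tibble(
    config = names(configs),
    mean_accuracy = vapply(reports, function(r) mean(r$folds$accuracy),
                           numeric(1), USE.NAMES = FALSE),
    std_accuracy = vapply(reports, function(r) pop_sd(r$folds$accuracy),
                          numeric(1), USE.NAMES = FALSE),
    p_vs_baseline = c(NA_real_, vapply(reports[-1], function(r) {
      wilcoxon_signed_rank(r$folds$accuracy, base_acc)$p_value
    }, numeric(1), USE.NAMES = FALSE)),
    report = unname(reports))
}
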