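test_that("depthwise-pointwise layer is causal, compact and exact at k = 1", {
  set.seed(21)
  Cn <- 8; T <- 40
  x <- matrix(rnorm(Cn * T), Cn, T)
  Wd <- matrix(rnorm(Cn * 3), Cn, 3)
  Wp <- matrix(rnorm(Cn * Cn), Cn, Cn)

  # causality: perturbing time t never changes outputs before t
  y0 <- dwpw_causal_conv(x, Wd, Wp, dilation = 2)
  for (t in sample(2:T, 10)) {
    xp <- x
    xp[, t] <- xp[, t] + rnorm(Cn)
    yp <- dwpw_causal_conv(xp, Wd, Wp, dilation = 2)
    expect_identical(yp[, seq_len(t - 1), drop = FALSE],
                     y0[, seq_len(t - 1), drop = FALSE])
  }

  # parameter factorization: 32 -> 32 at k = 3 costs 1120 vs 3072 standard
  expect_equal(dwpw_param_count(32, 32, 3), 1120)
  expect_equal(32 * 32 * 3, 3072)

  # k = 1 with identity pointwise weights is the identity map
  y_id <- dwpw_causal_conv(x, matrix(1, Cn, 1), diag(Cn), dilation = 1)
  expect_equal(y_id, x, tolerance = 1e-12)
})

test_that("depthwise-pointwise layer matches a brute-force convolution oracle", {
  set.seed(22)
  c_in <- 3; c_out <- 5; k <- 3; d <- 2; T <- 20
  x <- matrix(rnorm(c_in * T), c_in, T)
  Wd <- matrix(rnorm(c_in * k), c_in, k)
  Wp <- matrix(rnorm(c_out * c_in), c_out, c_in)
  y <- dwpw_causal_conv(x, Wd, Wp, dilation = d)
  oracle <- matrix(0, c_out, T)
  for (t in seq_len(T)) {
    z <- numeric(c_in)
    for (c in seq_len(c_in)) {
      for (j in 0:(k - 1)) {
        ti <- t - j * d
        if (ti >= 1) z[c] <- z[c] + Wd[c, j + 1] * x[c, ti]
      }
    }
    oracle[, t] <- Wp %*% z
  }
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("squeeze-and-excitation gates are per-channel scalars in (0, 1)", {
  set.seed(23)
  Cn <- 8; r <- 4
  x <- matrix(rnorm(Cn * 30), Cn, 30)
  w1 <- matrix(rnorm(Cn / r * Cn, sd = 0.5), Cn / r, Cn)
  w2 <- matrix(rnorm(Cn * Cn / r, sd = 0.5), Cn, Cn / r)
  y <- se_gate(x, w1, rep(0, Cn / r), w2, rep(0, Cn))
  g <- attr(y, "gate")
  expect_true(all(g > 0 & g < 1))
  ratio <- y / x
  for (c in seq_len(Cn)) {
    expect_equal(stats::sd(ratio[c, ]), 0, tolerance = 1e-12)
    expect_equal(ratio[c, 1], g[c], tolerance = 1e-12)
  }
  # all-zero input stays zero; huge pre-activations approach the identity
  expect_equal(unclass(se_gate(matrix(0, Cn, 5), w1, rep(0, Cn / r),
                               w2, rep(0, Cn)))[, ],
               matrix(0, Cn, 5), ignore_attr = TRUE)
  y_sat <- se_gate(x, matrix(0, Cn / r, Cn), rep(0, Cn / r),
                   matrix(0, Cn, Cn / r), rep(100, Cn))
  expect_equal(unclass(y_sat)[, ], x, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("forward pass honours the shape contract in every fusion mode", {
  x <- array(rnorm(4 * 64 * 2), c(4, 64, 2))
  for (fusion in c("parallel", "serial", "cnn_only", "tcn_only")) {
    cfg <- model_config(64, 10, fusion = fusion)
    m <- init_model(cfg, seed = 3)
    lg <- forward(m, x)
    expect_equal(dim(lg), c(4, 10))
    expect_true(all(is.finite(lg)))
    expect_identical(lg, forward(m, x))       # eval mode is deterministic
  }
  cfg <- model_config(64, 10)
  m <- init_model(cfg, 1)
  expect_error(forward(m, array(0, c(4, 32, 2))), "expected input")
  # extreme input magnitudes stay finite thanks to batch norm
  big <- forward(m, array(1e3 * rnorm(4 * 64 * 2), c(4, 64, 2)))
  expect_true(all(is.finite(big)))
})

test_that("parameter counts grow with input length and shrink with factorization", {
  n64 <- count_parameters(model_config(64, 10))
  n128 <- count_parameters(model_config(128, 10))
  expect_lt(n64, n128)

  # the cnn_only variant is the CNN branch plus the head
  n_cnn <- count_parameters(model_config(64, 10, fusion = "cnn_only"))
  expect_lt(n_cnn, n64)

  # a dwpw TCN stack is smaller than the standard-convolution equivalent
  dw <- dwpw_param_count(32, 32, 3)
  expect_lt(dw, 32 * 32 * 3)
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("eyewrite")
  set.seed(42)
  cfg <- model_config(16, 3, tcn = list(dropout = 0), head = list(dropout = 0))
  m <- init_model(cfg, seed = 7)
  layers <- ns$model_layers(m)
  B <- 4
  x <- array(rnorm(2 * 16 * B), c(2, 16, B))
  yidx <- sample(3, B, replace = TRUE)
  loss_fn <- function() {
    lg <- ns$model_fw(m, x, training = TRUE)
    p <- t(ns$softmax_rows(t(lg)))
    -mean(log(pmax(p[cbind(yidx, seq_len(B))], 1e-12)))
  }
  lg <- ns$model_fw(m, x, training = TRUE)
  p <- t(ns$softmax_rows(t(lg)))
  onehot <- matrix(0, 3, B)
  onehot[cbind(yidx, seq_len(B))] <- 1
  ns$model_bw(m, (p - onehot) / B)
  h <- 1e-5
  set.seed(99)
  for (l in layers) {
    for (pn in l$params) {
      w <- get(pn, envir = l)
      g <- get(paste0("d", pn), envir = l)
      for (i in sample(length(w), min(3, length(w)))) {
        w0 <- w[i]
        w[i] <- w0 + h; assign(pn, w, envir = l); lp <- loss_fn()
        w[i] <- w0 - h; assign(pn, w, envir = l); lm <- loss_fn()
        w[i] <- w0; assign(pn, w, envir = l)
        num <- (lp - lm) / (2 * h)
        expect_equal(g[i], num, tolerance = 1e-3,
                     label = sprintf("grad of %s[%d] in %s layer", pn, i, l$type))
      }
    }
  }
})

test_that("model checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- model_config(64, 10)
  m <- init_model(cfg, seed = 5)
  x <- array(rnorm(2 * 64 * 2), c(2, 64, 2))
  before <- forward(m, x)
  path <- file.path(dir, "ck.rds")
  save_model(m, path)
  m2 <- load_model(path, cfg)
  expect_equal(forward(m2, x), before, tolerance = 1e-12)
  expect_error(load_model(path, model_config(64, 12)), "fingerprint")
})
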