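# Internal neural-network primitives.
#
# Feature maps are numeric arrays of dim c(C, T, B): channels first, then
# time, then batch. With channels on the fastest-varying dimension, channel
# mixing is a single BLAS matmul on matrix(x, C, T*B), and per-channel
# scaling uses R's recycling (array * length-C vector). Layers are mutable
# environments holding parameters, gradients and forward caches; `ly_fw()` /
# `ly_bw()` dispatch on `l$type`.

zeros_like <- function(x) array(0, dim(x))

pad_time <- function(x, left, right, value = 0) {
  d <- dim(x)
  if (left == 0 && right == 0) return(x)
  out <- array(value, c(d[1], d[2] + left + right, d[3]))
  out[, (left + 1):(left + d[2]), ] <- x
  out
}

fanin_init <- function(dims, fan_in) {
  n <- prod(dims)
  b <- 1 / sqrt(fan_in)
  w <- runif(n, -b, b)
  if (length(dims) > 1) array(w, dims) else w
}

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- character(0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  l
}

# ---- standard 1-D convolution (length-preserving "same" padding) ----

make_conv1d <- function(c_in, c_out, k, bias = TRUE) {
  fan_in <- c_in * k
  l <- new_layer("conv1d", c_in = c_in, c_out = c_out, k = k,
                 W = fanin_init(c(c_out, c_in, k), fan_in),
                 b = if (bias) fanin_init(c_out, fan_in) else NULL,
                 pad_l = (k - 1L) %/% 2L, pad_r = k - 1L - (k - 1L) %/% 2L)
  l$params <- if (bias) c("W", "b") else "W"
  l
}

conv1d_fw <- function(l, x) {
  d <- dim(x)
  res <- conv1d_fw_cpp(x, matrix(l$W, l$c_out, l$c_in * l$k), l$b, l$k, l$pad_l)
  l$cache_xcol <- res$xcol
  res$y
}

conv1d_bw <- function(l, dy) {
  res <- conv1d_bw_cpp(l$cache_xcol, matrix(l$W, l$c_out, l$c_in * l$k), dy,
                       l$c_in, l$k, l$pad_l, !is.null(l$b))
  l$dW <- array(res$dW, dim(l$W))
  if (!is.null(l$b)) l$db <- res$db
  res$dx
}

# ---- depthwise-pointwise dilated causal convolution ----

make_dwpw <- function(c_in, c_out, k, dilation) {
  l <- new_layer("dwpw", c_in = c_in, c_out = c_out, k = k, d = dilation,
                 Wd = fanin_init(c(c_in, k), k),
                 Wp = fanin_init(c(c_out, c_in), c_in))
  l$params <- c("Wd", "Wp")
  l
}

dwpw_fw <- function(l, x) {
  res <- dwpw_fw_cpp(x, l$Wd, l$Wp, l$d)
  l$cache_x <- x
  l$cache_z <- res$z
  res$y
}

dwpw_bw <- function(l, dy) {
  res <- dwpw_bw_cpp(l$cache_x, l$cache_z, l$Wd, l$Wp, l$d, dy)
  l$dWd <- res$dWd
  l$dWp <- res$dWp
  res$dx
}

# ---- batch normalization over (time, batch) per channel ----

make_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("bn", c = c, eps = eps, momentum = momentum,
                 gamma = rep(1, c), beta = rep(0, c),
                 run_mean = rep(0, c), run_var = rep(1, c))
  l$params <- c("gamma", "beta")
  l
}

bn_fw <- function(l, x, training) {
  d <- dim(x); n <- d[2] * d[3]
  if (training) {
    res <- bn_fw_cpp(x, l$gamma, l$beta, l$eps)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * res$mean
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * res$var * n / max(n - 1, 1)
    l$cache_xhat <- res$xhat; l$cache_invstd <- res$invstd
    res$y
  } else {
    xm <- matrix(x, l$c, n)
    xhat <- (xm - l$run_mean) / sqrt(l$run_var + l$eps)
    array(xhat * l$gamma + l$beta, d)
  }
}

bn_bw <- function(l, dy) {
  res <- bn_bw_cpp(l$cache_xhat, l$cache_invstd, l$gamma, dy)
  l$dgamma <- res$dgamma
  l$dbeta <- res$dbeta
  res$dx
}

# ---- activations / dropout ----

make_act <- function(kind) new_layer("act", kind = kind)

act_fw <- function(l, x) {
  if (l$kind == "relu") {
    l$cache_x <- x
    return(relu_fw_cpp(x))
  }
  y <- elu_fw_cpp(x)
  l$cache_y <- y
  y
}

act_bw <- function(l, dy) {
  if (l$kind == "relu") relu_bw_cpp(l$cache_x, dy) else elu_bw_cpp(l$cache_y, dy)
}

make_dropout <- function(p) new_layer("dropout", p = p)

dropout_fw <- function(l, x, training) {
  if (!training || l$p <= 0) { l$cache_mask <- NULL; return(x) }
  res <- dropout_fw_cpp(x, l$p)
  l$cache_mask <- res$mask
  res$y
}

dropout_bw <- function(l, dy) {
  if (is.null(l$cache_mask)) dy else dropout_bw_cpp(l$cache_mask, dy)
}

# ---- max pooling (kernel k, stride s, symmetric zero-count padding p) ----

pool_out_len <- function(T, k = 3L, s = 2L, p = 1L) (T + 2L * p - k) %/% s + 1L

make_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_layer("maxpool", k = k, s = stride, p = pad)
}

maxpool_fw <- function(l, x) {
  res <- maxpool_fw_cpp(x, l$k, l$s, l$p)
  l$cache_src <- res$src
  l$cache_T <- dim(x)[2]
  res$y
}

maxpool_bw <- function(l, dy) {
  maxpool_bw_cpp(l$cache_src, dy, l$cache_T)
}

# ---- squeeze-and-excitation channel gate ----

make_se <- function(c, reduction) {
  if (c %% reduction != 0) abort("SE channel count must be divisible by the reduction.")
  h <- c %/% reduction
  l <- new_layer("se", c = c, h = h,
                 W1 = fanin_init(c(h, c), c), b1 = rep(0, h),
                 W2 = fanin_init(c(c, h), h), b2 = rep(0, c))
  l$params <- c("W1", "b1", "W2", "b2")
  l
}

squeeze_means <- function(x) {
  d <- dim(x)
  vapply(seq_len(d[3]), function(b) rowMeans(x[, , b, drop = FALSE][, , 1]),
         numeric(d[1]))
}

expand_gate <- function(g, T, B) {
  array(g[, rep(seq_len(B), each = T)], c(nrow(g), T, B))
}

se_fw <- function(l, x) {
  d <- dim(x); T <- d[2]; B <- d[3]
  s <- matrix(squeeze_means(x), l$c, B)
  z <- pmax(l$W1 %*% s + l$b1, 0)
  g <- 1 / (1 + exp(-(l$W2 %*% z + l$b2)))
  G <- expand_gate(g, T, B)
  l$cache_x <- x; l$cache_s <- s; l$cache_z <- z; l$cache_g <- g; l$cache_G <- G
  x * G
}

se_bw <- function(l, dy) {
  d <- dim(dy); T <- d[2]; B <- d[3]
  dx <- dy * l$cache_G
  dg <- matrix(squeeze_means(dy * l$cache_x), l$c, B) * T  # sum over time
  da2 <- dg * l$cache_g * (1 - l$cache_g)
  l$dW2 <- da2 %*% t(l$cache_z)
  l$db2 <- rowSums(da2)
  dz <- crossprod(l$W2, da2) * (l$cache_z > 0)
  l$dW1 <- dz %*% t(l$cache_s)
  l$db1 <- rowSums(dz)
  ds <- crossprod(l$W1, dz)
  dx + expand_gate(ds / T, T, B)
}

# ---- fully connected head ----

make_linear <- function(n_in, n_out) {
  l <- new_layer("linear", n_in = n_in, n_out = n_out,
                 W = fanin_init(c(n_out, n_in), n_in),
                 b = fanin_init(n_out, n_in))
  l$params <- c("W", "b")
  l
}

linear_fw <- function(l, xmat) {   # xmat: n_in x B
  l$cache_x <- xmat
  l$W %*% xmat + l$b
}

linear_bw <- function(l, dy) {
  l$dW <- dy %*% t(l$cache_x)
  l$db <- rowSums(dy)
  crossprod(l$W, dy)
}

# ---- generic dispatch ----

ly_fw <- function(l, x, training = FALSE) {
  switch(l$type,
    conv1d = conv1d_fw(l, x),
    dwpw = dwpw_fw(l, x),
    bn = bn_fw(l, x, training),
    act = act_fw(l, x),
    dropout = dropout_fw(l, x, training),
    maxpool = maxpool_fw(l, x),
    se = se_fw(l, x),
    linear = linear_fw(l, x))
}

ly_bw <- function(l, dy) {
  switch(l$type,
    conv1d = conv1d_bw(l, dy),
    dwpw = dwpw_bw(l, dy),
    bn = bn_bw(l, dy),
    act = act_bw(l, dy),
    dropout = dropout_bw(l, dy),
    maxpool = maxpool_bw(l, dy),
    se = se_bw(l, dy),
    linear = linear_bw(l, dy))
}
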