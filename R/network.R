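#' Hybrid 1D CNN-TCN model configuration
#'
#' Describes the hybrid classifier: a 1D CNN branch (two convolutions with
#' kernel 5 producing 16 then 32 feature maps, each followed by max pooling)
#' in parallel with a TCN branch (three residual blocks of depthwise-
#' pointwise dilated causal convolutions, kernel 3, 32 channels, dilations
#' 1/2/4, ELU activations and dropout, capped by a squeeze-and-excitation
#' gate). Branch outputs are concatenated channel-wise at matched temporal
#' length, then batch-normalized, dropped out, flattened and mapped to class
#' logits by a linear layer.
#'
#' @param input_length Input sequence length L (trajectories are length-
#'   normalized to this before entering the model).
#' @param n_classes Number of classes C (>= 2).
#' @param in_channels Input channels (2: the x and y coordinates).
#' @param fusion `"parallel"` (concatenate branch features), `"serial"`
#'   (CNN output fed into the TCN branch), `"cnn_only"` or `"tcn_only"`.
#' @param cnn List with `kernel`, `channels` (length 2), `pool_kernel`,
#'   `pool_stride`, `pool_padding`. The default pool stride is 2, which
#'   halves the temporal resolution at each pooling as the architecture
#'   intends; stride 1 is accepted and keeps the length unchanged.
#' @param tcn List with `kernel`, `channels`, `dilations`, `dropout`,
#'   `se_reduction`.
#' @param head List with `dropout`.
#' @return A list of class `eyw_model_config`.
#' @export
model_config <- function(input_length = 64, n_classes = 10, in_channels = 2,
                         fusion = c("parallel", "serial", "cnn_only", "tcn_only"),
                         cnn = list(), tcn = list(), head = list()) {
  cnn <- utils::modifyList(list(kernel = 5L, channels = c(16L, 32L),
                                pool_kernel = 3L, pool_stride = 2L,
                                pool_padding = 1L), cnn)
  tcn <- utils::modifyList(list(kernel = 3L, channels = 32L,
                                dilations = c(1L, 2L, 4L), dropout = 0.3,
                                se_reduction = 4L), tcn)
  head <- utils::modifyList(list(dropout = 0.3), head)
  if (input_length < 4) abort("`input_length` must be >= 4.")
  if (n_classes < 2) abort("`n_classes` must be >= 2.")
  if (tcn$dropout < 0 || tcn$dropout >= 1 || head$dropout < 0 || head$dropout >= 1) {
    abort("dropout rates must lie in [0, 1).")
  }
  structure(list(input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 fusion = match.arg(fusion), cnn = cnn, tcn = tcn, head = head),
            class = "eyw_model_config")
}

pool_spec <- function(cfg) list(k = cfg$cnn$pool_kernel, s = cfg$cnn$pool_stride,
                                p = cfg$cnn$pool_padding)

branch_out_len <- function(T, cfg, n_pools = 2L) {
  ps <- pool_spec(cfg)
  for (i in seq_len(n_pools)) T <- pool_out_len(T, ps$k, ps$s, ps$p)
  T
}

make_cnn_branch <- function(cfg) {
  ps <- pool_spec(cfg)
  ch <- cfg$cnn$channels
  list(conv1 = make_conv1d(cfg$in_channels, ch[1], cfg$cnn$kernel, bias = TRUE),
       act1 = make_act("relu"),
       pool1 = make_maxpool(ps$k, ps$s, ps$p),
       conv2 = make_conv1d(ch[1], ch[2], cfg$cnn$kernel, bias = FALSE),
       bn2 = make_bn(ch[2]),
       act2 = make_act("relu"),
       pool2 = make_maxpool(ps$k, ps$s, ps$p))
}

# One TCN residual block: two (dwpw conv -> BN -> ELU [-> pool] -> dropout)
# stages sharing a dilation, plus a skip path (1x1 projection when channel
# counts differ) pooled in step with the main path.
make_tcn_block <- function(c_in, c_out, k, dilation, dropout, pooled, ps) {
  list(conv_a = make_dwpw(c_in, c_out, k, dilation),
       bn_a = make_bn(c_out),
       act_a = make_act("elu"),
       drop_a = make_dropout(dropout),
       conv_b = make_dwpw(c_out, c_out, k, dilation),
       bn_b = make_bn(c_out),
       act_b = make_act("elu"),
       pool = if (pooled) make_maxpool(ps$k, ps$s, ps$p) else NULL,
       drop_b = make_dropout(dropout),
       proj = if (c_in != c_out) make_conv1d(c_in, c_out, 1L, bias = FALSE) else NULL,
       skip_pool = if (pooled) make_maxpool(ps$k, ps$s, ps$p) else NULL)
}

make_tcn_branch <- function(cfg, in_channels) {
  ps <- pool_spec(cfg)
  dil <- cfg$tcn$dilations
  ch <- cfg$tcn$channels
  n <- length(dil)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    # the first n-1 blocks pool so the branch reaches the CNN branch's length
    blocks[[i]] <- make_tcn_block(if (i == 1) in_channels else ch, ch,
                                  cfg$tcn$kernel, dil[i], cfg$tcn$dropout,
                                  pooled = i < n, ps = ps)
  }
  list(blocks = blocks, se = make_se(ch, cfg$tcn$se_reduction))
}

#' Initialize a hybrid CNN-TCN model
#'
#' Creates the layer graph for a [model_config()] with fan-in uniform weight
#' initialization under the given seed, so leave-one-subject-out runs are
#' reproducible fold by fold.
#'
#' @param cfg An [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `eyw_model`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "eyw_model_config"))
  set.seed(seed)
  L <- cfg$input_length
  m <- list(cfg = cfg)
  if (cfg$fusion %in% c("parallel", "serial", "cnn_only")) {
    m$cnn <- make_cnn_branch(cfg)
  }
  if (cfg$fusion %in% c("parallel", "serial", "tcn_only")) {
    tcn_in <- if (cfg$fusion == "serial") cfg$cnn$channels[2] else cfg$in_channels
    m$tcn <- make_tcn_branch(cfg, tcn_in)
  }
  T_cnn <- branch_out_len(L, cfg)
  head_T <- switch(cfg$fusion,
    parallel = T_cnn, cnn_only = T_cnn, tcn_only = T_cnn,
    serial = branch_out_len(T_cnn, cfg))
  head_C <- switch(cfg$fusion,
    parallel = cfg$cnn$channels[2] + cfg$tcn$channels,
    cnn_only = cfg$cnn$channels[2],
    serial = cfg$tcn$channels,
    tcn_only = cfg$tcn$channels)
  m$head <- list(bn = make_bn(head_C),
                 drop = make_dropout(cfg$head$dropout),
                 fc = make_linear(head_C * head_T, cfg$n_classes))
  m$head_T <- head_T
  m$head_C <- head_C
  structure(m, class = "eyw_model")
}

model_layers <- function(model) {
  out <- list()
  grab <- function(x) {
    if (is.environment(x)) out[[length(out) + 1]] <<- x
    else if (is.list(x)) for (el in x) grab(el)
  }
  grab(model$cnn); grab(model$tcn); grab(model$head)
  out
}

cnn_branch_fw <- function(br, x, training) {
  x <- ly_fw(br$conv1, x); x <- ly_fw(br$act1, x); x <- ly_fw(br$pool1, x)
  x <- ly_fw(br$conv2, x); x <- ly_fw(br$bn2, x, training)
  x <- ly_fw(br$act2, x); ly_fw(br$pool2, x)
}

cnn_branch_bw <- function(br, dy) {
  dy <- ly_bw(br$pool2, dy); dy <- ly_bw(br$act2, dy); dy <- ly_bw(br$bn2, dy)
  dy <- ly_bw(br$conv2, dy); dy <- ly_bw(br$pool1, dy); dy <- ly_bw(br$act1, dy)
  ly_bw(br$conv1, dy)
}

tcn_block_fw <- function(bl, x, training) {
  h <- ly_fw(bl$conv_a, x); h <- ly_fw(bl$bn_a, h, training)
  h <- ly_fw(bl$act_a, h); h <- ly_fw(bl$drop_a, h, training)
  h <- ly_fw(bl$conv_b, h); h <- ly_fw(bl$bn_b, h, training)
  h <- ly_fw(bl$act_b, h)
  if (!is.null(bl$pool)) h <- ly_fw(bl$pool, h)
  h <- ly_fw(bl$drop_b, h, training)
  s <- if (is.null(bl$proj)) x else ly_fw(bl$proj, x)
  if (!is.null(bl$skip_pool)) s <- ly_fw(bl$skip_pool, s)
  h + s
}

tcn_block_bw <- function(bl, dy) {
  ds <- dy
  if (!is.null(bl$skip_pool)) ds <- ly_bw(bl$skip_pool, ds)
  dx_skip <- if (is.null(bl$proj)) ds else ly_bw(bl$proj, ds)
  dh <- ly_bw(bl$drop_b, dy)
  if (!is.null(bl$pool)) dh <- ly_bw(bl$pool, dh)
  dh <- ly_bw(bl$act_b, dh); dh <- ly_bw(bl$bn_b, dh); dh <- ly_bw(bl$conv_b, dh)
  dh <- ly_bw(bl$drop_a, dh); dh <- ly_bw(bl$act_a, dh); dh <- ly_bw(bl$bn_a, dh)
  ly_bw(bl$conv_a, dh) + dx_skip
}

tcn_branch_fw <- function(br, x, training) {
  for (bl in br$blocks) x <- tcn_block_fw(bl, x, training)
  ly_fw(br$se, x)
}

tcn_branch_bw <- function(br, dy) {
  dy <- ly_bw(br$se, dy)
  for (bl in rev(br$blocks)) dy <- tcn_block_bw(bl, dy)
  dy
}

#' Forward pass of the hybrid model
#'
#' @param model An [init_model()] result.
#' @param x Input batch: an array of dim `c(B, L, 2)` (B trajectories of
#'   L x 2 coordinates), a single L x 2 matrix, or a list of trajectories.
#' @param training Logical; training mode uses batch statistics for batch
#'   normalization and samples dropout masks, evaluation mode is
#'   deterministic.
#' @return A B x C matrix of class logits.
#' @export
forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "eyw_model"))
  x <- as_input_array(x, model$cfg)
  h <- model_fw(model, x, training)
  t(h)
}

# convert user-facing input forms to the internal c(C, T, B) layout
as_input_array <- function(x, cfg) {
  L <- cfg$input_length
  if (is.list(x) && !is.array(x)) {
    x <- simplify2array(lapply(x, function(tr) traj_matrix(as_trajectory(tr))))
    # now L x 2 x B -> want 2 x L x B
    if (dim(x)[1] != L) {
      abort(sprintf("expected trajectories of length %d, got %d.", L, dim(x)[1]))
    }
    return(aperm(x, c(2, 1, 3)))
  }
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  d <- dim(x)
  if (length(d) != 3 || d[2] != L || d[3] != cfg$in_channels) {
    abort(sprintf("expected input of shape B x %d x %d, got %s.",
                  L, cfg$in_channels, paste(d, collapse = " x ")))
  }
  aperm(x, c(3, 2, 1))
}

model_fw <- function(model, x, training) {      # x: C x T x B -> logits C_cls x B
  cfg <- model$cfg
  B <- dim(x)[3]
  feat <- switch(cfg$fusion,
    parallel = {
      a <- cnn_branch_fw(model$cnn, x, training)
      b <- tcn_branch_fw(model$tcn, x, training)
      out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], B))
      out[seq_len(dim(a)[1]), , ] <- a
      out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
      out
    },
    serial = tcn_branch_fw(model$tcn, cnn_branch_fw(model$cnn, x, training), training),
    cnn_only = cnn_branch_fw(model$cnn, x, training),
    tcn_only = tcn_branch_fw(model$tcn, x, training))
  h <- ly_fw(model$head$bn, feat, training)
  h <- ly_fw(model$head$drop, h, training)
  ly_fw(model$head$fc, matrix(h, model$head_C * model$head_T, B))
}

model_bw <- function(model, dlogits) {          # dlogits: C_cls x B
  cfg <- model$cfg
  B <- ncol(dlogits)
  dh <- ly_bw(model$head$fc, dlogits)
  dh <- array(dh, c(model$head_C, model$head_T, B))
  dh <- ly_bw(model$head$drop, dh)
  dfeat <- ly_bw(model$head$bn, dh)
  switch(cfg$fusion,
    parallel = {
      ca <- cfg$cnn$channels[2]
      da <- dfeat[seq_len(ca), , , drop = FALSE]
      db <- dfeat[ca + seq_len(cfg$tcn$channels), , , drop = FALSE]
      cnn_branch_bw(model$cnn, da)
      tcn_branch_bw(model$tcn, db)
    },
    serial = cnn_branch_bw(model$cnn, tcn_branch_bw(model$tcn, dfeat)),
    cnn_only = cnn_branch_bw(model$cnn, dfeat),
    tcn_only = tcn_branch_bw(model$tcn, dfeat))
  invisible(NULL)
}

#' Depthwise-pointwise dilated causal convolution of a feature map
#'
#' Applies one dilated causal filter of `k` taps to each input channel
#' independently (depthwise step), then mixes channels with a 1x1
#' convolution (pointwise step). The input is padded on the left only with
#' `(k - 1) * dilation` zeros, so the output at time t depends exclusively
#' on inputs at times <= t. The factorization uses
#' `C_in * k + C_in * C_out` weights against `C_in * C_out * k` for a
#' standard convolution.
#'
#' @param x Numeric matrix `C_in x T`.
#' @param depthwise Numeric matrix `C_in x k` of per-channel filter taps;
#'   column j holds the tap reaching back `(j - 1) * dilation` samples.
#' @param pointwise Numeric matrix `C_out x C_in` of 1x1 mixing weights.
#' @param dilation Positive integer dilation.
#' @return Numeric matrix `C_out x T`.
#' @export
dwpw_causal_conv <- function(x, depthwise, pointwise, dilation = 1L) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  c_in <- nrow(x)
  if (nrow(depthwise) != c_in || ncol(pointwise) != c_in) {
    abort("weight shapes do not match the input channel count.")
  }
  l <- make_dwpw(c_in, nrow(pointwise), ncol(depthwise), as.integer(dilation))
  l$Wd <- depthwise
  l$Wp <- pointwise
  y <- dwpw_fw(l, array(x, c(c_in, ncol(x), 1L)))
  matrix(y, nrow(pointwise), ncol(x))
}

#' Number of weights in a depthwise-pointwise layer
#'
#' @param c_in,c_out Channel counts.
#' @param k Kernel size.
#' @return `c_in * k + c_in * c_out` (no biases), versus
#'   `c_in * c_out * k` for the standard convolution it replaces.
#' @export
dwpw_param_count <- function(c_in, c_out, k) c_in * k + c_in * c_out

#' Squeeze-and-excitation channel gate
#'
#' Computes per-channel statistics by global average pooling over time,
#' passes them through a bottleneck (C -> C/reduction -> C) with ReLU then
#' sigmoid, and rescales each channel of the input by its gate in (0, 1).
#'
#' @param x Numeric matrix `C x T`.
#' @param w1,b1 Bottleneck weights (`C/r x C`) and bias.
#' @param w2,b2 Expansion weights (`C x C/r`) and bias.
#' @return The gated feature map, same shape as `x`; the gate values are
#'   attached as attribute `"gate"`.
#' @export
se_gate <- function(x, w1, b1, w2, b2) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  s <- rowMeans(x)
  z <- pmax(as.numeric(w1 %*% s + b1), 0)
  g <- 1 / (1 + exp(-as.numeric(w2 %*% z + b2)))
  structure(x * g, gate = g)
}

#' Count learnable parameters of a model configuration
#'
#' @param cfg An [model_config()].
#' @return Integer count of learnable scalars (batch-norm scale/shift
#'   included; running statistics excluded).
#' @export
count_parameters <- function(cfg) {
  model <- init_model(cfg, seed = 0L)
  sum(vapply(model_layers(model), function(l) {
    sum(vapply(l$params, function(p) length(get(p, envir = l)), numeric(1)))
  }, numeric(1)))
}
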