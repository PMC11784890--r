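#' Fold a batch-norm stage into convolution weights
#'
#' Given convolution weights `(cin, kh, kw, cout)`, an optional bias and the
#' normalization statistics, returns weights and bias such that
#' `conv(x; w', b') == bn(conv(x; w, b))` exactly in real arithmetic.
#' Arithmetic is done in double precision.
#'
#' @param weights convolution kernel, dim `(cin, kh, kw, cout)`.
#' @param bias length-`cout` bias (or NULL for zero).
#' @param norm_stats list with `mean`, `var`, `scale` (gamma), `shift` (beta),
#'   `eps`, each per output channel (scalars recycle).
#' @return list with elements `weights` and `bias`.
#' @export
fuse_conv_bn <- function(weights, bias, norm_stats) {
  d <- dim(weights)
  cout <- d[4]
  s <- norm_stats
  mean <- rep(s$mean, length.out = cout)
  var <- rep(s$var, length.out = cout)
  scale <- rep(s$scale %||% 1, length.out = cout)
  shift <- rep(s$shift %||% 0, length.out = cout)
  eps <- s$eps %||% 0
  if (any(var + eps <= 0)) stop("variance + eps must be positive")
  if (is.null(bias)) bias <- numeric(cout)
  if (length(bias) != cout) stop("bias length must match output channels")
  f <- scale / sqrt(var + eps)
  w2 <- sweep(weights, 4, f, "*")
  list(weights = w2, bias = shift + (bias - mean) * f)
}

#' Express average pooling as an equivalent convolution kernel
#'
#' A `k x k`, stride-1, zero-padded average pooling over `channels` channels
#' equals a convolution whose kernel maps each channel to itself with every
#' tap `1/k^2`.
#'
#' @param k odd pooling window.
#' @param channels channel count.
#' @return kernel array of dim `(channels, k, k, channels)`.
#' @export
avgpool_to_conv <- function(k, channels) {
  if (k %% 2 == 0) stop("pooling window must be odd")
  w <- array(0, c(channels, k, k, channels))
  for (c in seq_len(channels)) w[c, , , c] <- 1 / k^2
  w
}

#' Merge a 1x1 convolution followed by a 3x3 convolution into one kernel
#'
#' The composition of a pointwise channel map and a 3x3 convolution is itself
#' a 3x3 convolution; this computes its kernel (and, via `b1`/`b3`, its bias,
#' valid everywhere when the intermediate border is padded with the 1x1
#' stage's offset, as the training-time branch does).
#'
#' @param w1x1 kernel `(cin, 1, 1, mid)`.
#' @param w3x3 kernel `(mid, 3, 3, cout)`.
#' @param b1,b3 optional biases of the two stages.
#' @return list with `weights` `(cin, 3, 3, cout)` and `bias`.
#' @export
merge_1x1_then_3x3 <- function(w1x1, w3x3, b1 = NULL, b3 = NULL) {
  d1 <- dim(w1x1); d3 <- dim(w3x3)
  if (d1[4] != d3[1]) stop("channel chain mismatch: 1x1 outputs ", d1[4],
                           ", 3x3 expects ", d3[1])
  cin <- d1[1]; mid <- d1[4]; cout <- d3[4]
  wm <- matrix(w1x1, cin, mid) %*% matrix(w3x3, mid)
  dim(wm) <- c(cin, 3L, 3L, cout)
  if (is.null(b1)) b1 <- numeric(mid)
  if (is.null(b3)) b3 <- numeric(cout)
  m3 <- w3x3; dim(m3) <- c(mid, 9L, cout)
  bsum <- as.vector(t(apply(m3, c(1, 3), sum)) %*% b1) + b3
  list(weights = wm, bias = bsum)
}

embed_1x1_center <- function(w1x1) {
  d <- dim(w1x1)
  w <- array(0, c(d[1], 3L, 3L, d[4]))
  w[, 2, 2, ] <- w1x1
  w
}

bn_stats_of <- function(gamma, beta, state, eps) {
  list(mean = state$running_mean, var = state$running_var,
       scale = val(gamma), shift = val(beta), eps = eps)
}

#' Collapse a diverse-branch convolution into a single 3x3 kernel
#'
#' Sums the 3x3-equivalent kernels of the four training branches (1x1 kernels
#' embedded at the center tap, the 1x1->3x3 sequence merged, average pooling
#' expressed as a fixed kernel), each with its batch norm folded in using the
#' stored running statistics. The result has exactly the parameter count of a
#' plain 3x3 convolution with bias.
#'
#' @param m a diverse-branch module as built inside [c2f_block()] with
#'   `dbb = TRUE`.
#' @return list with `weights` `(cin, 3, 3, cout)` and `bias` (length `cout`).
#' @export
dbb_fuse <- function(m) {
  stopifnot(inherits(m, "dbb"))
  fm <- fuse_conv_bn(val(m$main$w), NULL,
                     bn_stats_of(m$main$gamma, m$main$beta, m$main$state, m$main$eps))
  f1 <- fuse_conv_bn(val(m$b1x1$w), NULL,
                     bn_stats_of(m$b1x1$gamma, m$b1x1$beta, m$b1x1$state, m$b1x1$eps))
  s1 <- fuse_conv_bn(val(m$s1$w), NULL,
                     bn_stats_of(m$s1$gamma, m$s1$beta, m$s1$state, m$s1$eps))
  s2 <- fuse_conv_bn(val(m$s2$w), NULL,
                     bn_stats_of(m$s2$gamma, m$s2$beta, m$s2$state, m$s2$eps))
  sq <- merge_1x1_then_3x3(s1$weights, s2$weights, s1$bias, s2$bias)
  av <- fuse_conv_bn(avgpool_to_conv(3L, m$cin), NULL,
                     bn_stats_of(m$avg_gamma, m$avg_beta, m$avg_state, m$eps))
  list(weights = fm$weights + embed_1x1_center(f1$weights) + sq$weights + av$weights,
       bias = fm$bias + f1$bias + sq$bias + av$bias)
}

#' Re-parameterize a module tree for deployment
#'
#' Recursively folds every batch norm into its convolution and collapses
#' every diverse-branch convolution into a single 3x3 convolution with bias.
#' The returned tree computes the same eval-mode function (exactly, in real
#' arithmetic) with the parameter count of the plain architecture. Fusing an
#' already-fused tree is a no-op.
#'
#' @param m a module (layer, block, or whole detector).
#' @return the fused module.
#' @export
fuse_module <- function(m) UseMethod("fuse_module")

#' @export
fuse_module.cv <- function(m) {
  if (is.null(m$gamma)) return(m)  # already deploy form
  f <- fuse_conv_bn(val(m$w), if (is.null(m$b)) NULL else val(m$b),
                    bn_stats_of(m$gamma, m$beta, m$state, m$eps))
  out <- m
  out$w <- ad_param(f$weights)
  out$b <- ad_param(f$bias)
  out$gamma <- NULL; out$beta <- NULL; out$state <- NULL
  out
}

#' @export
fuse_module.dbb <- function(m) {
  f <- dbb_fuse(m)
  new_module("cv",
    w = ad_param(f$weights), b = ad_param(f$bias),
    gamma = NULL, beta = NULL, state = NULL,
    cin = m$cin, cout = m$cout, k = 3L, stride = 1L, pad = 1L,
    act = m$act, eps = m$eps)
}

#' @export
fuse_module.default <- function(m) {
  if (!is.list(m)) return(m)
  out <- m
  for (i in seq_along(m)) {
    el <- m[[i]]
    if (inherits(el, "pd_module")) out[[i]] <- fuse_module(el)
    else if (is.list(el) && !is_node(el)) out[[i]] <- fuse_module.default(el)
  }
  if (inherits(m, "c2f")) out$fused <- TRUE
  out
}

# does any sub-module still carry un-fused structure?
is_fused <- function(m) {
  ok <- TRUE
  walk <- function(x) {
    if (inherits(x, "dbb")) ok <<- FALSE
    else if (inherits(x, "cv")) { if (!is.null(x$gamma)) ok <<- FALSE }
    if (is.list(x) && !is_node(x)) for (el in x) walk(el)
  }
  walk(m)
  ok
}

#' Run a block forward on a plain array
#'
#' Convenience wrapper around the internal forward pass: takes and returns
#' plain numeric arrays in CHWN layout. `mode = "deploy"` requires the module
#' to have been fused with [fuse_module()] first and errors otherwise;
#' `"train"` uses batch statistics in the normalization layers, `"eval"` the
#' running ones.
#'
#' @param m a module such as a [c2f_block()].
#' @param x numeric array, dim `(channels, height, width, batch)`.
#' @param mode `"eval"`, `"train"` or `"deploy"`.
#' @return numeric array of the block's output.
#' @export
module_forward <- function(m, x, mode = c("eval", "train", "deploy")) {
  mode <- match.arg(mode)
  if (mode == "deploy" && !is_fused(m))
    stop("deploy mode requested but the module has un-fused branches; call fuse_module() first")
  val(fwd(m, x, training = (mode == "train")))
}

#' @rdname c2f_block
#' @details `cfb_block()` is the diverse-branch variant: a [c2f_block()] whose
#'   bottleneck convolutions are four-branch re-parameterizable convolutions.
#' @export
cfb_block <- function(cin, cout, n = 1L, shortcut = TRUE, dbb_convs = "both") {
  c2f_block(cin, cout, n, shortcut, dbb = TRUE, dbb_convs = dbb_convs)
}
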