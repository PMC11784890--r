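# Parameterized layers. A module is a list with a class attribute; trainable
# parameters are `ad_param` nodes stored (possibly nested) inside it, so
# copying the module list preserves parameter identity (nodes are
# environments). `fwd()` dispatches the forward pass; `training` toggles
# batch-norm statistics.

new_module <- function(.cls, ...) structure(list(...), class = c(.cls, "pd_module"))

fwd <- function(m, ...) UseMethod("fwd")

bn_state <- function(cout) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(cout)
  st$running_var <- rep(1, cout)
  st
}

#' Convolution + batch norm + SiLU building block
#'
#' The standard detector convolution: a `k x k` convolution with
#' shape-preserving padding, batch normalization and SiLU activation. Deploy
#' (fused) instances carry a bias and no normalization.
#'
#' @param cin,cout channel counts; `k` odd kernel size; `stride` integer.
#' @param act apply SiLU after normalization.
#' @param bn include a batch-norm stage (dropped in fused instances).
#' @param bias include an additive bias (used when `bn = FALSE`).
#' @param pad explicit padding (default `k %/% 2`, shape-preserving).
#' @return a module usable with the package's forward/fusion machinery.
#' @keywords internal
conv_layer <- function(cin, cout, k = 1L, stride = 1L, act = TRUE, bn = TRUE,
                       bias = !bn, pad = NULL) {
  stopifnot(k %% 2 == 1)
  w <- ad_param(array(stats::rnorm(cin * k * k * cout, sd = sqrt(2 / (cin * k * k))),
                      c(cin, k, k, cout)))
  new_module("cv",
    w = w,
    b = if (bias) ad_param(numeric(cout)) else NULL,
    gamma = if (bn) ad_param(rep(1, cout)) else NULL,
    beta = if (bn) ad_param(numeric(cout)) else NULL,
    state = if (bn) bn_state(cout) else NULL,
    cin = cin, cout = cout, k = k, stride = stride,
    pad = pad %||% (k %/% 2L), act = act, eps = 1e-5)
}

fwd.cv <- function(m, x, training = FALSE, ...) {
  y <- ad_conv2d(x, m$w, m$b, stride = m$stride, pad = m$pad)
  if (!is.null(m$gamma))
    y <- ad_batchnorm(y, m$gamma, m$beta, m$state, training, eps = m$eps)
  if (m$act) y <- ad_silu(y) else y
}

#' Diverse-branch convolution
#'
#' Training-time structure of the re-parameterizable convolution: four
#' parallel branches -- a 3x3 convolution, a 1x1 convolution, a 1x1 -> 3x3
#' sequence, and 3x3 average pooling -- each followed by its own batch
#' normalization, summed and passed through SiLU. [dbb_fuse()] collapses the
#' four branches into one 3x3 convolution with bias.
#'
#' @param cin,cout channel counts; must be equal (the average-pooling branch
#'   preserves channels) and `stride` must be 1.
#' @keywords internal
dbb_layer <- function(cin, cout, stride = 1L) {
  if (stride != 1L) stop("diverse-branch convolution requires stride 1 (the average-pooling branch has no strided equivalent)")
  if (cin != cout) stop("diverse-branch convolution requires cin == cout")
  new_module("dbb",
    main = conv_layer(cin, cout, 3L, act = FALSE),
    b1x1 = conv_layer(cin, cout, 1L, act = FALSE),
    # the sequence branch pads its input first so the 1x1 stage's affine
    # offset propagates into the border taps exactly as the merged kernel does
    s1 = conv_layer(cin, cin, 1L, act = FALSE, pad = 0L),
    s2 = conv_layer(cin, cout, 3L, act = FALSE, pad = 0L),
    avg_gamma = ad_param(rep(1, cout)),
    avg_beta = ad_param(numeric(cout)),
    avg_state = bn_state(cout),
    cin = cin, cout = cout, k = 3L, stride = 1L, pad = 1L,
    act = TRUE, eps = 1e-5)
}

fwd.dbb <- function(m, x, training = FALSE, ...) {
  y <- ad_add(fwd(m$main, x, training), fwd(m$b1x1, x, training))
  s <- fwd(m$s2, fwd(m$s1, ad_pad(x, 1L), training), training)
  a <- ad_batchnorm(ad_avgpool3_s1(x), m$avg_gamma, m$avg_beta, m$avg_state,
                    training, eps = m$eps)
  y <- ad_add(ad_add(y, s), a)
  if (m$act) ad_silu(y) else y
}

bottleneck_layer <- function(c, shortcut = TRUE, dbb = FALSE,
                             dbb_convs = c("both", "first")) {
  dbb_convs <- match.arg(dbb_convs)
  mk <- function(use_dbb) if (use_dbb) dbb_layer(c, c) else conv_layer(c, c, 3L)
  new_module("bottleneck",
    cv1 = mk(dbb), cv2 = mk(dbb && dbb_convs == "both"),
    shortcut = shortcut, ch = c)
}

fwd.bottleneck <- function(m, x, training = FALSE, ...) {
  y <- fwd(m$cv2, fwd(m$cv1, x, training), training)
  if (m$shortcut) ad_add(x, y) else y
}

#' C2f / CFB split-bottleneck block
#'
#' The split - n bottlenecks - concat - project topology: a 1x1 convolution
#' doubles into two half-width streams, one stream passes through `n`
#' residual bottlenecks whose intermediate outputs are all retained, and the
#' concatenation is projected back to `cout`. With `dbb = TRUE` the bottleneck
#' convolutions are diverse-branch convolutions (the CFB variant), which
#' [fuse_module()] collapses back to the plain-C2f parameter layout.
#'
#' @param cin,cout channel counts.
#' @param n number of bottlenecks.
#' @param shortcut residual add inside each bottleneck.
#' @param dbb use diverse-branch bottleneck convolutions (CFB).
#' @param dbb_convs replace `"both"` bottleneck convolutions or only the
#'   `"first"`.
#' @export
c2f_block <- function(cin, cout, n = 1L, shortcut = TRUE, dbb = FALSE,
                      dbb_convs = "both") {
  ch <- cout %/% 2L
  new_module("c2f",
    cv1 = conv_layer(cin, 2L * ch, 1L),
    cv2 = conv_layer((2L + n) * ch, cout, 1L),
    blocks = lapply(seq_len(n), function(i)
      bottleneck_layer(ch, shortcut, dbb, dbb_convs)),
    ch = ch, cin = cin, cout = cout, n = n, dbb = dbb, fused = FALSE)
}

fwd.c2f <- function(m, x, training = FALSE, ...) {
  y <- fwd(m$cv1, x, training)
  parts <- list(ad_slice_c(y, seq_len(m$ch)),
                ad_slice_c(y, m$ch + seq_len(m$ch)))
  cur <- parts[[2]]
  for (b in m$blocks) {
    cur <- fwd(b, cur, training)
    parts <- c(parts, list(cur))
  }
  fwd(m$cv2, ad_concat_c(parts), training)
}

sppf_layer <- function(c, k = 5L) {
  ch <- c %/% 2L
  new_module("sppf",
    cv1 = conv_layer(c, ch, 1L),
    cv2 = conv_layer(4L * ch, c, 1L),
    k = k)
}

fwd.sppf <- function(m, x, training = FALSE, ...) {
  y <- fwd(m$cv1, x, training)
  p1 <- ad_maxpool_s1(y, m$k)
  p2 <- ad_maxpool_s1(p1, m$k)
  p3 <- ad_maxpool_s1(p2, m$k)
  fwd(m$cv2, ad_concat_c(list(y, p1, p2, p3)), training)
}

## ---- token-space layers ----------------------------------------------------

fc_layer <- function(din, dout, bias = TRUE) {
  new_module("fc",
    w = ad_param(matrix(stats::rnorm(din * dout, sd = sqrt(1 / din)), din, dout)),
    b = if (bias) ad_param(numeric(dout)) else NULL,
    din = din, dout = dout)
}

fwd.fc <- function(m, x, ...) ad_linear(x, m$w, m$b)

ln_layer <- function(d) {
  new_module("ln", gamma = ad_param(rep(1, d)), beta = ad_param(numeric(d)), d = d)
}

fwd.ln <- function(m, x, ...) ad_layernorm_rows(x, m$gamma, m$beta)

mlp_layer <- function(dims, act = "relu") {
  new_module("mlp",
    layers = lapply(seq_len(length(dims) - 1L), function(i)
      fc_layer(dims[i], dims[i + 1L])),
    act = act)
}

fwd.mlp <- function(m, x, ...) {
  nl <- length(m$layers)
  for (i in seq_len(nl)) {
    x <- fwd(m$layers[[i]], x)
    if (i < nl) x <- switch(m$act, relu = ad_relu(x), silu = ad_silu(x))
  }
  x
}

mha_layer <- function(d, nhead) {
  stopifnot(d %% nhead == 0)
  new_module("mha",
    wq = fc_layer(d, d), wk = fc_layer(d, d), wv = fc_layer(d, d),
    wo = fc_layer(d, d), d = d, nhead = nhead, dh = d %/% nhead)
}

# q, k, v: token matrices (nodes); standard scaled dot-product attention
# (single fused tape node for speed)
fwd.mha <- function(m, q, k, v, ...) {
  ad_mha_fused(q, k, v, m$wq$w, m$wq$b, m$wk$w, m$wk$b,
               m$wv$w, m$wv$b, m$wo$w, m$wo$b, m$nhead)
}

# multiply each row of x (n x d) by the matching element of s (length-n node)
ad_colmul <- function(x, s) {
  xv <- val(x); sv <- val(s)
  ad_node(xv * as.vector(sv), function(g) {
    acc(x, g * as.vector(sv))
    acc(s, rowSums(g * xv))
  })
}

# multi-scale deformable attention: each query samples `npoints` bilinear
# locations per head per pyramid level around its reference box and mixes
# them with softmax weights predicted from the query itself.
deform_attn_layer <- function(d, nhead, nlevels = 3L, npoints = 4L) {
  new_module("deform",
    w_off = fc_layer(d, nhead * nlevels * npoints * 2L),
    w_att = fc_layer(d, nhead * nlevels * npoints),
    w_val = fc_layer(d, d),
    w_out = fc_layer(d, d),
    d = d, nhead = nhead, nlevels = nlevels, npoints = npoints,
    dh = d %/% nhead)
}

# q: (Q x d) node; values: list of per-level (H*W x d) nodes; shapes: list of
# c(h, w); ref: plain (Q x 4) cxcywh matrix in [0,1] (treated as constant)
fwd.deform <- function(m, q, values, shapes, ref, ...) {
  nq <- nrow(val(q))
  off <- fwd(m$w_off, q)
  attl <- fwd(m$w_att, q)
  vproj <- lapply(values, function(v) fwd(m$w_val, v))
  lp <- m$nlevels * m$npoints
  heads <- vector("list", m$nhead)
  for (h in seq_len(m$nhead)) {
    aw <- ad_softmax_rows(ad_cols(attl, (h - 1L) * lp + seq_len(lp)))
    hsum <- NULL
    for (l in seq_len(m$nlevels)) {
      vh <- ad_cols(vproj[[l]], (h - 1L) * m$dh + seq_len(m$dh))
      for (p in seq_len(m$npoints)) {
        blk <- ((h - 1L) * m$nlevels + (l - 1L)) * m$npoints + (p - 1L)
        oxy <- ad_cols(off, c(2L * blk + 1L, 2L * blk + 2L))
        # sample at ref center + scaled offset (offset in units of half box)
        coords <- ad_add(ad_mul(oxy, ref[, 3:4] * (0.5 / m$npoints)), ref[, 1:2])
        smp <- ad_bilinear_rows(vh, coords, shapes[[l]][1], shapes[[l]][2])
        w_lp <- ad_cols(aw, (l - 1L) * m$npoints + p)
        term <- ad_colmul(smp, w_lp)
        hsum <- if (is.null(hsum)) term else ad_add(hsum, term)
      }
    }
    heads[[h]] <- hsum
  }
  fwd(m$w_out, ad_cbind(heads))
}

ffn_layer <- function(d, dff) {
  new_module("ffn", fc1 = fc_layer(d, dff), fc2 = fc_layer(dff, d))
}

fwd.ffn <- function(m, x, ...) fwd(m$fc2, ad_relu(fwd(m$fc1, x)))

## ---- parameter bookkeeping -------------------------------------------------

#' Collect all trainable parameter nodes inside a module tree
#' @param m a module (possibly nested lists of modules).
#' @return flat list of `ad_param` nodes.
#' @export
collect_params <- function(m) {
  out <- list()
  walk <- function(x) {
    if (is_node(x)) {
      if (isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(m)
  out
}

#' Number of trainable parameters in a module tree
#' @param m a module.
#' @export
n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$v), 0))
}
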