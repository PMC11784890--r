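#' Detector configuration
#'
#' Assembles the hyperparameters of the hybrid detector: a YOLOv8-style
#' convolutional backbone (stem + four downsampling stages with split-
#' bottleneck blocks + SPPF pooling) feeding a single-layer AIFI transformer
#' encoder on the deepest map, a top-down/bottom-up fusion neck, and a
#' six-layer query decoder head that predicts a fixed set of boxes with no
#' non-maximum suppression.
#'
#' `scale = "l"` is the full-size configuration (640x640 input, 256-d hidden,
#' 300 queries, multi-scale deformable decoder attention with 4 sampling
#' points). `scale = "tiny"` is a small CPU-friendly configuration
#' (8/16/32-channel backbone, 32-d hidden, dense decoder attention) used for
#' end-to-end tests and the overfit demonstration.
#'
#' @param scale `"l"` or `"tiny"`.
#' @param nc number of object classes.
#' @param cfb replace the backbone's stage-2 and stage-6 split-bottleneck
#'   blocks with re-parameterizable diverse-branch (CFB) blocks.
#' @param lfpn use the LFPN neck: CARAFE content-aware upsampling plus
#'   FEM/FSM channel enhancement on the lateral branches. Otherwise the
#'   baseline neck upsamples by nearest neighbour and keeps plain laterals.
#' @param loss bounding-box regression loss name.
#' @param loss_par a [loss_params()].
#' @param n_queries,img_size,top_k optional overrides of the scale defaults.
#' @return a config list consumed by [build_detector()].
#' @export
detector_config <- function(scale = c("l", "tiny"), nc = 5L, cfb = FALSE,
                            lfpn = FALSE,
                            loss = c("simiou", "giou", "eiou", "siou"),
                            loss_par = loss_params(),
                            n_queries = NULL, img_size = NULL, top_k = NULL) {
  scale <- match.arg(scale)
  loss <- match.arg(loss)
  base <- switch(scale,
    l = list(widths = c(64L, 128L, 256L, 512L, 512L), depths = c(3L, 6L, 6L, 3L),
             hidden = 256L, nhead = 8L, ffn = 1024L, dec_layers = 6L,
             n_queries = 300L, img_size = 640L, top_k = 100L,
             attn = "deform", dec_points = 4L, repc3_n = 3L),
    tiny = list(widths = c(8L, 16L, 32L, 32L, 32L), depths = c(1L, 1L, 1L, 1L),
                hidden = 32L, nhead = 4L, ffn = 64L, dec_layers = 6L,
                n_queries = 30L, img_size = 160L, top_k = 10L,
                attn = "dense", dec_points = 4L, repc3_n = 1L))
  base$scale <- scale
  base$nc <- as.integer(nc)
  base$cfb <- isTRUE(cfb)
  base$lfpn <- isTRUE(lfpn)
  base$loss <- loss
  base$loss_par <- loss_par
  if (!is.null(n_queries)) base$n_queries <- as.integer(n_queries)
  if (!is.null(img_size)) base$img_size <- as.integer(img_size)
  if (!is.null(top_k)) base$top_k <- as.integer(top_k)
  if (base$top_k > base$n_queries) stop("top_k cannot exceed n_queries")
  structure(base, class = "detector_config")
}

## ---- RepConv / RepC3 (neck fusion blocks) ----------------------------------

repconv_layer <- function(c) {
  new_module("repconv",
    conv3 = conv_layer(c, c, 3L, act = FALSE),
    conv1 = conv_layer(c, c, 1L, act = FALSE),
    ch = c)
}

fwd.repconv <- function(m, x, training = FALSE, ...) {
  ad_silu(ad_add(fwd(m$conv3, x, training), fwd(m$conv1, x, training)))
}

#' @export
fuse_module.repconv <- function(m) {
  f3 <- fuse_conv_bn(val(m$conv3$w), NULL,
                     bn_stats_of(m$conv3$gamma, m$conv3$beta, m$conv3$state, m$conv3$eps))
  f1 <- fuse_conv_bn(val(m$conv1$w), NULL,
                     bn_stats_of(m$conv1$gamma, m$conv1$beta, m$conv1$state, m$conv1$eps))
  new_module("cv",
    w = ad_param(f3$weights + embed_1x1_center(f1$weights)),
    b = ad_param(f3$bias + f1$bias),
    gamma = NULL, beta = NULL, state = NULL,
    cin = m$ch, cout = m$ch, k = 3L, stride = 1L, pad = 1L,
    act = TRUE, eps = 1e-5)
}

repc3_layer <- function(cin, cout, n = 3L) {
  new_module("repc3",
    cv1 = conv_layer(cin, cout, 1L),
    cv2 = conv_layer(cin, cout, 1L),
    blocks = lapply(seq_len(n), function(i) repconv_layer(cout)),
    n = n)
}

fwd.repc3 <- function(m, x, training = FALSE, ...) {
  y <- fwd(m$cv1, x, training)
  for (b in m$blocks) y <- fwd(b, y, training)
  ad_add(y, fwd(m$cv2, x, training))
}

## ---- backbone ---------------------------------------------------------------

#' Build the convolutional backbone
#'
#' Strided stem, four conv/C2f stages and SPPF pooling; emits feature maps at
#' strides 8, 16 and 32. With `cfb = TRUE` in the config, the stage-2 and
#' stage-6 blocks (in the standard layer numbering of the architecture sketch)
#' are CFB diverse-branch blocks.
#'
#' @param cfg a [detector_config()].
#' @return a backbone module; run with [forward_pyramid()].
#' @export
build_backbone <- function(cfg) {
  w <- cfg$widths; d <- cfg$depths
  new_module("backbone",
    stem = conv_layer(3L, w[1], 3L, stride = 2L),
    down1 = conv_layer(w[1], w[2], 3L, stride = 2L),
    c2f1 = c2f_block(w[2], w[2], d[1], shortcut = TRUE, dbb = cfg$cfb),
    down2 = conv_layer(w[2], w[3], 3L, stride = 2L),
    c2f2 = c2f_block(w[3], w[3], d[2], shortcut = TRUE),
    down3 = conv_layer(w[3], w[4], 3L, stride = 2L),
    c2f3 = c2f_block(w[4], w[4], d[3], shortcut = TRUE, dbb = cfg$cfb),
    down4 = conv_layer(w[4], w[5], 3L, stride = 2L),
    c2f4 = c2f_block(w[5], w[5], d[4], shortcut = TRUE),
    sppf = sppf_layer(w[5]))
}

fwd.backbone <- function(m, x, training = FALSE, ...) {
  d <- dim(x)
  if (d[2] %% 32 != 0 || d[3] %% 32 != 0)
    stop("backbone input spatial size must be divisible by 32 (letterbox first)")
  y <- fwd(m$stem, x, training)
  y <- fwd(m$c2f1, fwd(m$down1, y, training), training)
  p3 <- fwd(m$c2f2, fwd(m$down2, y, training), training)
  p4 <- fwd(m$c2f3, fwd(m$down3, p3, training), training)
  p5 <- fwd(m$sppf, fwd(m$c2f4, fwd(m$down4, p4, training), training), training)
  list(p3 = p3, p4 = p4, p5 = p5)
}

#' @rdname build_backbone
#' @param backbone a module from `build_backbone()`.
#' @param x image batch array, dim `(3, H, W, N)`, values in `[0, 1]`,
#'   `H`/`W` divisible by 32.
#' @param mode forward mode as in [module_forward()].
#' @return list of arrays `p3`, `p4`, `p5` at strides 8/16/32.
#' @export
forward_pyramid <- function(backbone, x, mode = "eval") {
  if (mode == "deploy" && !is_fused(backbone))
    stop("deploy mode requested but the module has un-fused branches; call fuse_module() first")
  lapply(fwd(backbone, x, training = (mode == "train")), val)
}

## ---- AIFI encoder -----------------------------------------------------------

aifi_layer <- function(d, nhead, ffn) {
  new_module("aifi",
    attn = mha_layer(d, nhead),
    ln1 = ln_layer(d),
    ffn = ffn_layer(d, ffn),
    ln2 = ln_layer(d),
    d = d)
}

fwd.aifi <- function(m, x, training = FALSE, ...) {
  d <- dim(val(x))
  if (d[1] != m$d) stop("aifi: feature channels must equal model dim")
  pos <- sincos_pos_embed_2d(d[2], d[3], m$d)
  outs <- vector("list", d[4])
  for (n in seq_len(d[4])) {
    tok <- ad_image_tokens(x, n)
    q <- ad_add(tok, pos)
    a <- fwd(m$attn, q, q, tok)
    s <- fwd(m$ln1, ad_add(tok, a))
    s <- fwd(m$ln2, ad_add(s, fwd(m$ffn, s)))
    outs[[n]] <- s
  }
  ad_stack_tokens(outs, d[2], d[3])
}

#' Apply the single-layer AIFI encoder to the deepest feature map
#'
#' Flattens the map to tokens, adds the deterministic 2D sine-cosine position
#' coding, applies one post-norm transformer encoder layer (self-attention +
#' feed-forward) and reshapes back. Spatial shape is preserved.
#'
#' @param x array `(d, H, W, N)` with `d` equal to the layer's model dim.
#' @param layer an AIFI module (see [build_detector()]; `model$neck$aifi`).
#' @param mode forward mode.
#' @export
aifi_encode <- function(x, layer, mode = "eval") {
  stopifnot(inherits(layer, "aifi"))
  val(fwd(layer, x, training = (mode == "train")))
}

## ---- neck -------------------------------------------------------------------

neck_layer <- function(cfg) {
  hd <- cfg$hidden; w <- cfg$widths; n <- cfg$repc3_n
  new_module("neck",
    proj3 = conv_layer(w[3], hd, 1L, act = FALSE),
    proj4 = conv_layer(w[4], hd, 1L, act = FALSE),
    proj5 = conv_layer(w[5], hd, 1L, act = FALSE),
    aifi = aifi_layer(hd, cfg$nhead, cfg$ffn),
    lat5 = conv_layer(hd, hd, 1L),
    lat4 = conv_layer(hd, hd, 1L),
    up5 = if (cfg$lfpn) carafe_layer(hd) else NULL,
    up4 = if (cfg$lfpn) carafe_layer(hd) else NULL,
    fem4 = if (cfg$lfpn) fem_layer(hd) else NULL,
    fem3 = if (cfg$lfpn) fem_layer(hd) else NULL,
    fpn4 = repc3_layer(2L * hd, hd, n),
    fpn3 = repc3_layer(2L * hd, hd, n),
    down3 = conv_layer(hd, hd, 3L, stride = 2L),
    down4 = conv_layer(hd, hd, 3L, stride = 2L),
    pan4 = repc3_layer(2L * hd, hd, n),
    pan5 = repc3_layer(2L * hd, hd, n),
    hd = hd, lfpn = cfg$lfpn)
}

fwd.neck <- function(m, p3, p4, p5, training = FALSE, ...) {
  e5 <- fwd(m$aifi, fwd(m$proj5, p5, training), training)
  l5 <- fwd(m$lat5, e5, training)
  u5 <- if (m$lfpn) fwd(m$up5, l5, training) else ad_upsample2(l5)
  b4 <- fwd(m$proj4, p4, training)
  if (m$lfpn) b4 <- fwd(m$fem4, b4, training)
  f4 <- fwd(m$fpn4, ad_concat_c(list(u5, b4)), training)
  l4 <- fwd(m$lat4, f4, training)
  u4 <- if (m$lfpn) fwd(m$up4, l4, training) else ad_upsample2(l4)
  b3 <- fwd(m$proj3, p3, training)
  if (m$lfpn) b3 <- fwd(m$fem3, b3, training)
  o3 <- fwd(m$fpn3, ad_concat_c(list(u4, b3)), training)
  d3 <- fwd(m$down3, o3, training)
  o4 <- fwd(m$pan4, ad_concat_c(list(d3, l4)), training)
  d4 <- fwd(m$down4, o4, training)
  o5 <- fwd(m$pan5, ad_concat_c(list(d4, l5)), training)
  list(o3, o4, o5)
}

#' Fuse a backbone pyramid through the neck
#'
#' Projects the three backbone maps to the hidden width, encodes the deepest
#' one with AIFI, runs the top-down pathway (CARAFE upsampling and FEM lateral
#' enhancement when the neck is an LFPN; nearest-neighbour upsampling and
#' plain laterals otherwise) followed by the stride-2 bottom-up pass, and
#' returns the fused pyramid at unchanged strides.
#'
#' @param pyr list of arrays `p3`, `p4`, `p5` from [forward_pyramid()].
#' @param neck a neck module (`model$neck`).
#' @param mode forward mode.
#' @return list of three fused feature-map arrays at strides 8/16/32.
#' @export
lfpn_fuse <- function(pyr, neck, mode = "eval") {
  stopifnot(inherits(neck, "neck"))
  lapply(fwd(neck, pyr$p3, pyr$p4, pyr$p5, training = (mode == "train")), val)
}

## ---- query decoder ----------------------------------------------------------

decoder_block <- function(cfg) {
  hd <- cfg$hidden
  new_module("decblock",
    self_attn = mha_layer(hd, cfg$nhead),
    cross = if (cfg$attn == "deform")
      deform_attn_layer(hd, cfg$nhead, 3L, cfg$dec_points)
    else mha_layer(hd, cfg$nhead),
    ffn = ffn_layer(hd, cfg$ffn),
    ln1 = ln_layer(hd), ln2 = ln_layer(hd), ln3 = ln_layer(hd),
    attn = cfg$attn)
}

decoder_mod <- function(cfg) {
  hd <- cfg$hidden; q <- cfg$n_queries
  # reference boxes start on a regular grid with moderate extent
  side <- ceiling(sqrt(q))
  cx <- (((seq_len(q) - 1L) %% side) + 0.5) / side
  cy <- (((seq_len(q) - 1L) %/% side) + 0.5) / side
  ref0 <- cbind(cx, cy, rep(0.2, q), rep(0.2, q))
  ref0 <- pmin(pmax(ref0, 0.02), 0.98)
  bbox_heads <- lapply(seq_len(cfg$dec_layers), function(i) {
    h <- mlp_layer(c(hd, hd, hd, 4L))
    last <- h$layers[[3]]
    last$w$v[] <- 0; last$b$v[] <- 0  # start from the un-refined references
    h
  })
  score_heads <- lapply(seq_len(cfg$dec_layers), function(i) {
    f <- fc_layer(hd, cfg$nc)
    f$b$v[] <- -2  # low initial objectness, focal-loss convention
    f
  })
  new_module("decoder",
    tgt = ad_param(matrix(stats::rnorm(q * hd, sd = 0.1), q, hd)),
    ref = ad_param(matrix(stats::qlogis(ref0), q, 4L)),
    qpos = mlp_layer(c(4L, 2L * hd, hd)),
    layers = lapply(seq_len(cfg$dec_layers), function(i) decoder_block(cfg)),
    score_heads = score_heads,
    bbox_heads = bbox_heads,
    n_queries = q, nc = cfg$nc, n_layers = cfg$dec_layers, hd = hd)
}

# decode one image: mems = list of per-level (H*W x hd) token nodes
fwd.decoder <- function(m, mems, shapes, training = FALSE, ...) {
  dense_kpos <- NULL
  memall <- NULL
  if (m$layers[[1]]$attn == "dense") {
    memall <- ad_rbind(mems)
    dense_kpos <- do.call(rbind, lapply(shapes, function(s)
      sincos_pos_embed_2d(s[1], s[2], m$hd)))
  }
  tgt <- m$tgt
  ref_logits <- m$ref
  outs <- vector("list", m$n_layers)
  for (l in seq_len(m$n_layers)) {
    lay <- m$layers[[l]]
    refs <- stats::plogis(val(ref_logits))  # constant for attention plumbing
    qpos <- fwd(m$qpos, refs)
    q <- ad_add(tgt, qpos)
    sa <- fwd(lay$self_attn, q, q, tgt)
    tgt <- fwd(lay$ln1, ad_add(tgt, sa))
    q2 <- ad_add(tgt, qpos)
    ca <- if (lay$attn == "deform")
      fwd(lay$cross, q2, mems, shapes, refs)
    else
      fwd(lay$cross, q2, ad_add(memall, dense_kpos), memall)
    tgt <- fwd(lay$ln2, ad_add(tgt, ca))
    tgt <- fwd(lay$ln3, ad_add(tgt, fwd(lay$ffn, tgt)))
    ref_logits <- ad_add(ref_logits, fwd(m$bbox_heads[[l]], tgt))
    outs[[l]] <- list(logits = fwd(m$score_heads[[l]], tgt),
                      boxes = ad_sigmoid(ref_logits))
  }
  outs
}

## ---- full detector ----------------------------------------------------------

#' Build the full detector
#'
#' Instantiates backbone, neck and query decoder from a [detector_config()],
#' with all random initialization driven by `seed`.
#'
#' @param cfg a [detector_config()].
#' @param seed integer seed for parameter initialization.
#' @return a `palm_detector` model object.
#' @export
build_detector <- function(cfg, seed = 0L) {
  with_seed(seed, {
    structure(list(
      cfg = cfg,
      backbone = build_backbone(cfg),
      neck = neck_layer(cfg),
      decoder = decoder_mod(cfg)
    ), class = c("palm_detector", "pd_module"))
  })
}

# full batch forward: x (3, H, W, N) -> per-image list of per-layer outputs
detector_forward <- function(model, x, training = FALSE) {
  pyr <- fwd(model$backbone, x, training)
  fused <- fwd(model$neck, pyr$p3, pyr$p4, pyr$p5, training)
  shapes <- lapply(fused, function(f) dim(val(f))[2:3])
  nimg <- dim(x)[4]
  per_image <- vector("list", nimg)
  for (n in seq_len(nimg)) {
    mems <- lapply(fused, ad_image_tokens, n = n)
    per_image[[n]] <- fwd(model$decoder, mems, shapes, training)
  }
  list(per_image = per_image, shapes = shapes)
}

#' Run the query decoder on a fused feature pyramid
#'
#' Exposes the head in isolation: takes the fused pyramid of one image,
#' tokenizes it, and returns the six decoder layers' class logits and
#' normalized `cxcywh` boxes (deep-supervision outputs; the last entry is the
#' final prediction).
#'
#' @param model a `palm_detector`.
#' @param fused list of three fused feature-map arrays (batch size 1),
#'   e.g. from [lfpn_fuse()].
#' @return list of `n_layers` elements, each with `logits` (`Q x nc`) and
#'   `boxes` (`Q x 4`, in `[0,1]`).
#' @export
decode_queries <- function(model, fused) {
  shapes <- lapply(fused, function(f) dim(f)[2:3])
  mems <- lapply(fused, ad_image_tokens, n = 1L)
  outs <- fwd(model$decoder, mems, shapes, training = FALSE)
  lapply(outs, function(o) list(logits = val(o$logits), boxes = val(o$boxes)))
}

#' Count trainable parameters
#'
#' `mode = "deploy"` counts the re-parameterized model (all batch norms folded
#' into convolution biases, diverse-branch and RepConv branches collapsed),
#' which is the standard summary convention for re-parameterizable detectors;
#' `"train"` counts the training-time structure.
#'
#' @param model a model or module.
#' @param mode `"deploy"` or `"train"`.
#' @return integer parameter count; `param_millions()` formats it as millions
#'   rounded to 2 decimals.
#' @export
count_parameters <- function(model, mode = c("deploy", "train")) {
  mode <- match.arg(mode)
  if (mode == "deploy") model <- fuse_module(model)
  n_params(model)
}

#' @rdname count_parameters
#' @param n raw parameter count.
#' @export
param_millions <- function(n) round(n / 1e6, 2)

#' @export
fuse_module.palm_detector <- function(m) {
  out <- m
  out$backbone <- fuse_module(m$backbone)
  out$neck <- fuse_module(m$neck)
  out$decoder <- m$decoder  # token-space layers carry no fusible structure
  out
}

## ---- training objective ------------------------------------------------------

# sigmoid focal classification loss over all queries (node); target is a
# constant 0/1 matrix (Q x nc)
focal_loss_node <- function(logits, target, alpha = 0.25, gamma = 2) {
  p <- ad_sigmoid(logits)
  one_m_p <- ad_sub(1, p)
  pos <- ad_mul(ad_mul(ad_pow(one_m_p, gamma), ad_scale(ad_log(p), -1)),
                alpha * target)
  neg <- ad_mul(ad_mul(ad_pow(p, gamma), ad_scale(ad_log(one_m_p), -1)),
                (1 - alpha) * (1 - target))
  ad_sum(ad_add(pos, neg))
}

# composite box-regression loss on matched queries: forward uses the chosen
# IoU-family loss, backward uses central finite differences on the (piecewise
# smooth) loss surface, chained through the cxcywh -> xyxy map
ad_box_regression <- function(boxes_cxcywh, gt_xyxy, loss_name, params) {
  bv <- val(boxes_cxcywh)
  xyxy <- cxcywh_to_xyxy(bv)
  fn <- box_loss_by_name(loss_name)
  lv <- fn(xyxy, gt_xyxy, params)
  ad_node(sum(lv), function(g) {
    gx <- box_loss_grad(fn, xyxy, gt_xyxy, params) * g
    gc <- cbind(gx[, 1] + gx[, 3], gx[, 2] + gx[, 4],
                (gx[, 3] - gx[, 1]) / 2, (gx[, 4] - gx[, 2]) / 2)
    acc(boxes_cxcywh, gc)
  })
}

#' One optimization step of the detector
#'
#' Runs the batch forward in training mode, matches queries to ground truth
#' with [hungarian_match()] on the final decoder layer, accumulates the
#' objective over all decoder layers (deep supervision) -- sigmoid focal
#' classification on every query plus L1 and the configured IoU-family loss
#' on matched boxes -- backpropagates, and applies the optimizer.
#'
#' @param model a `palm_detector`.
#' @param batch list with `x` (image array `(3,H,W,N)`) and `targets` (per
#'   image: list with `boxes` as normalized corner-format matrix and
#'   `classes` as 1-based integer vector; empty matrices for background-only
#'   images).
#' @param opt optimizer from [adamw()] over `collect_params(model)`; if NULL
#'   the gradients are computed but no update applied.
#' @param w_cls,w_l1,w_box loss-term weights.
#' @return the scalar loss value (invisibly, with per-image losses as an
#'   attribute).
#' @export
training_step <- function(model, batch, opt = NULL,
                          w_cls = 1, w_l1 = 5, w_box = 2) {
  cfg <- model$cfg
  nimg <- dim(batch$x)[4]
  ad_begin_tape()
  out <- detector_forward(model, batch$x, training = TRUE)
  nl <- model$decoder$n_layers
  nq <- model$decoder$n_queries
  total <- NULL
  per_image <- numeric(nimg)
  for (i in seq_len(nimg)) {
    tg <- batch$targets[[i]]
    gtb <- as_box_matrix(tg$boxes %||% matrix(0, 0, 4))
    G <- nrow(gtb)
    fin <- out$per_image[[i]][[nl]]
    assign <- if (G > 0) {
      hungarian_match(stats::plogis(val(fin$logits)),
                      cxcywh_to_xyxy(val(fin$boxes)), gtb, tg$classes)
    } else integer(0)
    tmat <- matrix(0, nq, cfg$nc)
    if (G > 0) tmat[cbind(assign, tg$classes)] <- 1
    gtc <- if (G > 0) xyxy_to_cxcywh(gtb) else NULL
    norm <- max(1, G)
    img_loss <- NULL
    sels <- vector("list", nl)
    for (l in seq_len(nl)) {
      o <- out$per_image[[i]][[l]]
      cls <- ad_scale(focal_loss_node(o$logits, tmat), w_cls / norm)
      img_loss <- if (is.null(img_loss)) cls else ad_add(img_loss, cls)
      if (G > 0) sels[[l]] <- ad_rows(o$boxes, assign)
    }
    if (G > 0) {
      # all decoder layers' matched boxes in one stacked regression node
      sel <- ad_rbind(sels)
      gtc_all <- gtc[rep(seq_len(G), nl), , drop = FALSE]
      gtb_all <- gtb[rep(seq_len(G), nl), , drop = FALSE]
      l1 <- ad_scale(ad_sum(ad_abs(ad_sub(sel, gtc_all))), w_l1 / norm)
      bx <- ad_scale(ad_box_regression(sel, gtb_all, cfg$loss, cfg$loss_par),
                     w_box / norm)
      img_loss <- ad_add(img_loss, ad_add(l1, bx))
    }
    per_image[i] <- val(img_loss)
    total <- if (is.null(total)) img_loss else ad_add(total, img_loss)
  }
  loss <- ad_scale(total, 1 / nimg)
  if (!is.finite(val(loss))) {
    ad_end_tape()
    stop("non-finite training loss (", val(loss), "); per-image losses: ",
         paste(signif(per_image, 4), collapse = ", "))
  }
  ad_backward(loss)
  if (!is.null(opt)) opt$step()
  structure(invisible(val(loss)), per_image = per_image)
}

#' Train the detector on a fixed batch of images
#'
#' Full-batch gradient descent with AdamW and linear learning-rate warm-up.
#' All randomness derives from the model seed; the loop itself is
#' deterministic.
#'
#' @param model a `palm_detector`.
#' @param batch as in [training_step()].
#' @param steps number of optimization steps.
#' @param lr peak learning rate.
#' @param warmup linear warm-up steps.
#' @param weight_decay AdamW decoupled weight decay.
#' @param verbose print loss every `verbose` steps (0 = silent).
#' @return numeric vector of per-step losses.
#' @export
fit_detector <- function(model, batch, steps = 300L, lr = 1e-3, warmup = 20L,
                         weight_decay = 1e-4, verbose = 0L) {
  opt <- adamw(collect_params(model), lr = lr, weight_decay = weight_decay)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    opt$set_lr(if (s <= warmup) lr * s / warmup else lr)
    losses[s] <- training_step(model, batch, opt)
    if (verbose > 0 && s %% verbose == 0)
      message(sprintf("step %d loss %.4f", s, losses[s]))
  }
  losses
}

## ---- inference ---------------------------------------------------------------

#' Detect objects in an image
#'
#' Letterboxes the image to the model's input size, runs the NMS-free forward
#' pass, takes the `top_k` highest-scoring (query, class) predictions from the
#' final decoder layer, and maps the boxes back to original image
#' coordinates.
#'
#' @param object a `palm_detector`.
#' @param image numeric array `H x W x 3` with values in `[0, 1]`.
#' @param top_k number of detections to return (at most `n_queries`).
#' @param min_score drop detections below this score.
#' @param ... unused.
#' @return a data.frame with columns `x1, y1, x2, y2, class_id, score`,
#'   sorted by decreasing score (a detection record).
#' @export
predict.palm_detector <- function(object, image, top_k = NULL,
                                  min_score = 0, ...) {
  cfg <- object$cfg
  top_k <- top_k %||% cfg$top_k
  if (top_k > cfg$n_queries)
    stop("top_k (", top_k, ") exceeds the number of queries (", cfg$n_queries, ")")
  lb <- letterbox(image, target = cfg$img_size)
  x <- aperm(lb$image, c(3, 1, 2))
  dim(x) <- c(3L, cfg$img_size, cfg$img_size, 1L)
  out <- detector_forward(object, x, training = FALSE)
  fin <- out$per_image[[1]][[object$decoder$n_layers]]
  probs <- stats::plogis(val(fin$logits))
  boxes <- cxcywh_to_xyxy(val(fin$boxes)) * cfg$img_size
  score <- apply(probs, 1, max)
  cls <- apply(probs, 1, which.max)
  ord <- order(score, decreasing = TRUE)[seq_len(min(top_k, length(score)))]
  keep <- ord[score[ord] >= min_score]
  b <- letterbox_invert(boxes[keep, , drop = FALSE], lb)
  b <- box_clip(b, ncol(image[, , 1]), nrow(image[, , 1]))
  data.frame(x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
             class_id = cls[keep], score = score[keep])
}
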