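# Model assembly: backbone pyramid, AIFI, neck fusion, query decoding,
# Hungarian matching, the training objective, and NMS-free prediction.

tiny_model <- function(nc = 2, seed = 1, ...) {
  build_detector(detector_config("tiny", nc = nc, ...), seed = seed)
}

test_that("backbone emits strides 8/16/32 and validates input size", {
  cfg <- detector_config("tiny", nc = 2)
  bb <- palmdetr:::with_seed(1, build_backbone(cfg))
  x <- array(runif(3 * 160 * 160), c(3, 160, 160, 1))
  pyr <- forward_pyramid(bb, x)
  expect_equal(dim(pyr$p3)[2:3], c(20, 20))
  expect_equal(dim(pyr$p4)[2:3], c(10, 10))
  expect_equal(dim(pyr$p5)[2:3], c(5, 5))
  # fully convolutional: a different input size scales the maps
  x2 <- array(runif(3 * 320 * 320), c(3, 320, 320, 1))
  expect_equal(dim(forward_pyramid(bb, x2)$p3)[2:3], c(40, 40))
  expect_error(forward_pyramid(bb, array(0, c(3, 100, 100, 1))), "divisible by 32")
  # deterministic under fixed seed init
  bb2 <- palmdetr:::with_seed(1, build_backbone(cfg))
  expect_equal(forward_pyramid(bb2, x), pyr)
})

test_that("tiny-width forward runs quickly on cpu", {
  m <- tiny_model()
  x <- array(runif(3 * 160 * 160), c(3, 160, 160, 1))
  t0 <- Sys.time()
  out <- palmdetr:::detector_forward(m, x)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_length(out$per_image[[1]], 6)
})

test_that("aifi preserves shape, is batch-equivariant, and wires residuals", {
  cfg <- detector_config("tiny", nc = 2)
  m <- tiny_model()
  aifi <- m$neck$aifi
  x <- array(rnorm(32 * 5 * 5 * 3), c(32, 5, 5, 3))
  y <- aifi_encode(x, aifi)
  expect_equal(dim(y), dim(x))
  # permuting the batch permutes outputs identically
  xp <- x[, , , c(3, 1, 2)]
  yp <- aifi_encode(xp, aifi)
  expect_equal(yp, y[, , , c(3, 1, 2)])
  # channel mismatch is rejected
  expect_error(aifi_encode(array(0, c(16, 5, 5, 1)), aifi), "model dim")
  # with attention output and ffn silenced, the layer reduces to its
  # post-norm residual wiring: LN2(LN1(x))
  z <- aifi
  z$attn$wo$w$v[] <- 0; z$attn$wo$b$v[] <- 0
  z$ffn$fc2$w$v[] <- 0; z$ffn$fc2$b$v[] <- 0
  y0 <- aifi_encode(x, z)
  tok <- palmdetr:::ad_image_tokens(x, 1)
  ref <- palmdetr:::val(palmdetr:::fwd(z$ln2, palmdetr:::fwd(z$ln1, tok)))
  got <- palmdetr:::ad_image_tokens(y0, 1)
  expect_equal(palmdetr:::val(got), ref, tolerance = 1e-12)
})

test_that("neck fusion preserves pyramid sizes; carafe one-hot matches nearest", {
  m <- tiny_model(lfpn = TRUE)
  x <- array(runif(3 * 160 * 160 * 2), c(3, 160, 160, 2))
  pyr <- forward_pyramid(m$backbone, x)
  fused <- lfpn_fuse(pyr, m$neck)
  expect_equal(dim(fused[[1]])[2:3], dim(pyr$p3)[2:3])
  expect_equal(dim(fused[[2]])[2:3], dim(pyr$p4)[2:3])
  expect_equal(dim(fused[[3]])[2:3], dim(pyr$p5)[2:3])
  expect_equal(dim(fused[[1]])[1], m$cfg$hidden)
  # forcing the carafe kernels one-hot at the neighbourhood center makes the
  # content-aware upsampler coincide with nearest-neighbour upsampling
  up <- m$neck$up5
  up$encoder$w$v[] <- 0
  k2 <- up$cfg$k_up^2
  center <- (k2 + 1) %/% 2
  b <- numeric(k2 * up$cfg$scale^2)
  for (ph in 0:(up$cfg$scale^2 - 1)) b[center + k2 * ph] <- 50
  up$encoder$b$v <- b
  feat <- array(rnorm(32 * 5 * 5), c(32, 5, 5, 1))
  expect_equal(carafe_upsample(feat, up),
               palmdetr:::val(palmdetr:::ad_upsample2(feat)), tolerance = 1e-10)
})

test_that("gradient flows to every neck parameter (connectivity)", {
  m <- tiny_model(lfpn = TRUE, seed = 2)
  x <- array(runif(3 * 160 * 160), c(3, 160, 160, 1))
  palmdetr:::ad_begin_tape()
  pyr <- palmdetr:::fwd(m$backbone, x, training = TRUE)
  fused <- palmdetr:::fwd(m$neck, pyr$p3, pyr$p4, pyr$p5, training = TRUE)
  loss <- palmdetr:::ad_add(palmdetr:::ad_add(
    palmdetr:::ad_sum(fused[[1]]), palmdetr:::ad_sum(fused[[2]])),
    palmdetr:::ad_sum(fused[[3]]))
  palmdetr:::ad_backward(loss)
  ps <- collect_params(m$neck)
  got_grad <- vapply(ps, function(p) !is.null(p$g) && any(p$g != 0), logical(1))
  expect_true(all(got_grad))
  for (p in collect_params(m)) p$g <- NULL
})

test_that("decoder refines in [0,1], keeps references at zero refinement, and deep-supervises", {
  m <- tiny_model(seed = 5)
  x <- array(runif(3 * 160 * 160), c(3, 160, 160, 1))
  pyr <- forward_pyramid(m$backbone, x)
  fused <- lfpn_fuse(pyr, m$neck)
  outs <- decode_queries(m, fused)
  expect_length(outs, 6)
  for (o in outs) {
    expect_true(all(o$boxes >= 0 & o$boxes <= 1))
    expect_equal(dim(o$logits), c(m$cfg$n_queries, m$cfg$nc))
  }
  # the box-refinement heads start zero-initialized: every layer's boxes
  # equal the learned initial references
  ref <- stats::plogis(m$decoder$ref$v)
  expect_equal(outs[[6]]$boxes, ref, tolerance = 1e-12)
  expect_equal(outs[[1]]$boxes, ref, tolerance = 1e-12)
})

test_that("hungarian matching is one-to-one, minimal, and guards its inputs", {
  # single prediction, single target
  expect_equal(hungarian_match(matrix(0.9, 1, 1), matrix(c(0, 0, 1, 1), 1),
                               matrix(c(0, 0, 1, 1), 1), 1L), 1L)
  # empty ground truth -> empty assignment
  expect_length(hungarian_match(matrix(0.5, 3, 2), random_boxes(3, 1),
                                matrix(0, 0, 4), integer(0)), 0)
  expect_error(hungarian_match(matrix(0.5, 2, 2), random_boxes(2, 1),
                               random_boxes(3, 1), c(1L, 1L, 2L)),
               "more ground-truth")
  # matches exhaustive search on random instances for n_gt <= 6
  set.seed(51)
  perm <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))))
  for (trial in 1:25) {
    ng <- sample(2:5, 1); nq <- ng + sample(0:3, 1)
    cost <- matrix(runif(ng * nq), ng, nq)
    a <- solve_assignment(cost)
    expect_false(anyDuplicated(a) > 0)
    best <- Inf
    for (cols in utils::combn(nq, ng, simplify = FALSE))
      for (p in perm(cols))
        best <- min(best, sum(cost[cbind(seq_len(ng), p)]))
    expect_equal(sum(cost[cbind(seq_len(ng), a)]), best, tolerance = 1e-12)
  }
})

test_that("training objective: duplicates match, empties classify, losses stay finite", {
  m <- tiny_model(seed = 7)
  sc <- generate_scene(smoke_scene_spec(), seed = 100)
  xi <- aperm(sc$image, c(3, 1, 2)); dim(xi) <- c(3, 160, 160, 1)
  an <- sc$annotations
  b <- xywh_to_xyxy(as.matrix(an[, c("x", "y", "w", "h")])) / 160
  cls <- ifelse(an$category_id == 1L, 1L, 2L)
  x <- array(0, c(3, 160, 160, 3))
  x[, , , 1] <- xi; x[, , , 2] <- xi  # two identical images
  targets <- list(list(boxes = b, classes = cls),
                  list(boxes = b, classes = cls),
                  list(boxes = matrix(0, 0, 4), classes = integer(0)))
  loss <- training_step(m, list(x = x, targets = targets), opt = NULL)
  per <- attr(loss, "per_image")
  expect_true(is.finite(loss))
  expect_equal(per[1], per[2], tolerance = 1e-10)
  # background-only image contributes only (smaller) classification loss
  expect_lt(per[3], per[1])
  # gradients reached the backbone stem
  expect_false(is.null(m$backbone$stem$w$g))
  for (p in collect_params(m)) p$g <- NULL
})

test_that("prediction is NMS-free top-k with sorted scores inside the image", {
  m <- tiny_model(seed = 3)
  img <- generate_scene(smoke_scene_spec(), seed = 42)$image
  dets <- predict(m, img, top_k = 10)
  expect_lte(nrow(dets), 10)
  expect_true(all(diff(dets$score) <= 1e-12))
  expect_true(all(dets$x1 >= 0 & dets$y1 >= 0 & dets$x2 <= 160 & dets$y2 <= 160))
  expect_true(all(dets$class_id %in% 1:2))
  expect_error(predict(m, img, top_k = 500), "exceeds the number of queries")
})

test_that("parameter counting: closed forms and input-size invariance", {
  # plain 3x3 conv with bias, 2 in, 4 out
  cv <- palmdetr:::conv_layer(2, 4, 3, bn = FALSE, bias = TRUE)
  expect_equal(n_params(cv), 2 * 4 * 9 + 4)
  # counts are a property of the architecture, not the input resolution
  m1 <- build_detector(detector_config("tiny", nc = 2, img_size = 160), seed = 1)
  m2 <- build_detector(detector_config("tiny", nc = 2, img_size = 320), seed = 1)
  expect_identical(count_parameters(m1, "train"), count_parameters(m2, "train"))
  expect_identical(count_parameters(m1, "deploy"), count_parameters(m2, "deploy"))
  expect_gt(count_parameters(build_detector(detector_config("tiny", nc = 2, cfb = TRUE), 1), "train"),
            count_parameters(m1, "train"))
})

test_that("deformable attention gradients agree with finite differences", {
  set.seed(52)
  lyr <- palmdetr:::deform_attn_layer(8, 2, nlevels = 2, npoints = 2)
  vals <- list(matrix(rnorm(12 * 8), 12, 8), matrix(rnorm(6 * 8), 6, 8))
  shapes <- list(c(3, 4), c(2, 3))
  ref <- cbind(runif(4, 0.2, 0.8), runif(4, 0.2, 0.8), 0.3, 0.3)
  qv <- matrix(rnorm(4 * 8), 4, 8)
  mm <- matrix(rnorm(4 * 8), 4, 8)
  run <- function(qx) {
    qn <- palmdetr:::ad_param(qx)
    palmdetr:::ad_begin_tape()
    o <- palmdetr:::ad_sum(palmdetr:::ad_mul(
      palmdetr:::fwd(lyr, qn, lapply(vals, palmdetr:::ad_param), shapes, ref), mm))
    list(o = o, qn = qn)
  }
  r <- run(qv)
  palmdetr:::ad_backward(r$o)
  ga <- r$qn$g
  for (p in collect_params(lyr)) p$g <- NULL
  h <- 1e-6
  gn <- qv * 0
  for (i in seq_along(qv)) {
    qp <- qv; qp[i] <- qp[i] + h
    qm <- qv; qm[i] <- qm[i] - h
    vp <- run(qp)$o$v; palmdetr:::ad_end_tape()
    vm <- run(qm)$o$v; palmdetr:::ad_end_tape()
    gn[i] <- (vp - vm) / (2 * h)
  }
  expect_lt(max(abs(ga - gn)) / max(1, max(abs(gn))), 1e-5)
})
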