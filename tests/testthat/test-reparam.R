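# Structural re-parameterization: conv-BN folding, branch merging, and the
# train/deploy equivalence of the diverse-branch CFB blocks.

random_bn_stats <- function(cout) {
  list(mean = rnorm(cout), var = abs(rnorm(cout)) + 0.3,
       scale = rnorm(cout, 1, 0.3), shift = rnorm(cout, 0, 0.5), eps = 1e-5)
}

test_that("conv-bn folding is exact in real arithmetic", {
  # identity normalization leaves weights untouched
  w <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  f <- fuse_conv_bn(w, NULL, list(mean = 0, var = 1, scale = 1, shift = 0, eps = 0))
  expect_equal(f$weights, w)
  expect_equal(f$bias, rep(0, 4))
  # worked bias example: W=0, b=0, scale=2, shift=1, mean=0, var=1, eps=0
  f2 <- fuse_conv_bn(array(0, c(2, 3, 3, 2)), numeric(2),
                     list(mean = 0, var = 1, scale = 2, shift = 1, eps = 0))
  expect_equal(f2$weights, array(0, c(2, 3, 3, 2)))
  expect_equal(f2$bias, c(1, 1))
  expect_error(fuse_conv_bn(w, numeric(3), random_bn_stats(4)), "bias length")
})

test_that("folded conv+bn reproduces the normalized forward on random configs", {
  set.seed(21)
  worst <- 0
  for (trial in 1:100) {
    cin <- sample(1:4, 1); cout <- sample(1:4, 1)
    w <- array(rnorm(cin * 9 * cout), c(cin, 3, 3, cout))
    b <- rnorm(cout)
    st <- random_bn_stats(cout)
    x <- array(rnorm(cin * 5 * 5), c(cin, 5, 5, 1))
    y1 <- val(ad_conv2d(x, w, b))
    y1 <- sweep(sweep(y1, 1, st$mean), 1, sqrt(st$var + st$eps), "/")
    y1 <- sweep(sweep(y1, 1, st$scale, "*"), 1, st$shift, "+")
    f <- fuse_conv_bn(w, b, st)
    y2 <- val(ad_conv2d(x, f$weights, f$bias))
    worst <- max(worst, max(abs(y1 - y2)))
  }
  expect_lt(worst, 1e-10)
})

test_that("average pooling equals its all-1/k^2 convolution kernel", {
  w <- avgpool_to_conv(3, 2)
  expect_equal(w[1, , , 1], matrix(1 / 9, 3, 3))
  expect_equal(w[1, , , 2], matrix(0, 3, 3))  # channel map is diagonal
  expect_error(avgpool_to_conv(4, 2), "odd")
  # constant input stays constant in the interior; dual-forward agreement
  set.seed(22)
  x <- array(rnorm(2 * 6 * 7 * 2), c(2, 6, 7, 2))
  pooled <- val(ad_avgpool3_s1(x))
  conved <- val(ad_conv2d(x, w, NULL))
  expect_lt(max(abs(pooled - conved)), 1e-12)
  const <- array(4.2, c(2, 5, 5, 1))
  expect_equal(val(ad_avgpool3_s1(const))[1, 3, 3, 1], 4.2)
})

test_that("1x1 then 3x3 merging equals the composed convolution", {
  set.seed(23)
  # identity channel map leaves the 3x3 kernel unchanged
  w1 <- array(0, c(3, 1, 1, 3)); for (c in 1:3) w1[c, 1, 1, c] <- 1
  w3 <- array(rnorm(3 * 9 * 2), c(3, 3, 3, 2))
  mg <- merge_1x1_then_3x3(w1, w3)
  expect_equal(mg$weights, w3)
  # Dirac 3x3 embeds the 1x1 at the center
  w1b <- array(rnorm(2 * 4), c(2, 1, 1, 4))
  dirac <- array(0, c(4, 3, 3, 4)); for (c in 1:4) dirac[c, 2, 2, c] <- 1
  mg2 <- merge_1x1_then_3x3(w1b, dirac)
  expect_equal(mg2$weights[, 2, 2, ], w1b[, 1, 1, ])
  expect_equal(sum(abs(mg2$weights[, -2, , ])) + sum(abs(mg2$weights[, 2, c(1, 3), ])), 0)
  # dual-forward agreement with biases and the padded-intermediate semantics
  worst <- 0
  for (trial in 1:50) {
    cin <- sample(1:3, 1); mid <- sample(1:3, 1); cout <- sample(1:3, 1)
    w1r <- array(rnorm(cin * mid), c(cin, 1, 1, mid)); b1 <- rnorm(mid)
    w3r <- array(rnorm(mid * 9 * cout), c(mid, 3, 3, cout)); b3 <- rnorm(cout)
    x <- array(rnorm(cin * 6 * 6), c(cin, 6, 6, 1))
    xp <- val(ad_pad(x, 1L))
    t1 <- val(ad_conv2d(xp, w1r, b1, pad = 0L))
    y1 <- val(ad_conv2d(t1, w3r, b3, pad = 0L))
    m <- merge_1x1_then_3x3(w1r, w3r, b1, b3)
    y2 <- val(ad_conv2d(x, m$weights, m$bias))
    worst <- max(worst, max(abs(y1 - y2)))
  }
  expect_lt(worst, 1e-10)
  expect_error(merge_1x1_then_3x3(array(0, c(2, 1, 1, 3)), array(0, c(4, 3, 3, 2))),
               "chain mismatch")
})

test_that("diverse-branch fusion is a pure re-parameterization", {
  set.seed(24)
  worst <- 0
  for (trial in 1:30) {
    ch <- sample(2:6, 1)
    db <- dbb_layer(ch, ch)
    # move the running statistics off their init
    for (k in 1:2)
      invisible(module_forward(db, array(rnorm(ch * 8 * 8 * 2), c(ch, 8, 8, 2)), "train"))
    fz <- fuse_module(db)
    x <- array(rnorm(ch * 7 * 9 * 2), c(ch, 7, 9, 2))
    dev <- max(abs(module_forward(db, x, "eval") - module_forward(fz, x, "deploy")))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-10)  # double precision; well under the 1e-4 contract
})

test_that("dbb restrictions and fused layout", {
  expect_error(dbb_layer(4, 4, stride = 2), "stride 1")
  expect_error(dbb_layer(4, 6), "cin == cout")
  f <- fuse_module(dbb_layer(64, 64))
  expect_equal(n_params(f), 64 * 64 * 9 + 64)  # 36,928: plain 3x3 conv + bias
})

test_that("cfb block matches plain c2f after fusion, with zero overhead", {
  set.seed(25)
  cfb <- cfb_block(8, 8, n = 2)
  plain <- c2f_block(8, 8, n = 2)
  for (k in 1:3)
    invisible(module_forward(cfb, array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2)), "train"))
  fz <- fuse_module(cfb)
  x <- array(rnorm(8 * 10 * 12 * 2), c(8, 10, 12, 2))
  expect_lt(max(abs(module_forward(cfb, x, "eval") - module_forward(fz, x, "deploy"))),
            1e-10)
  # deploy parameter count equals the plain block's deploy count, exactly
  expect_identical(n_params(fz), n_params(fuse_module(plain)))
  # training-time branches cost extra parameters
  expect_gt(n_params(cfb), n_params(plain))
  # shape preservation and the unfused-deploy error contract
  expect_equal(dim(module_forward(cfb, x, "eval")), dim(x))
  expect_error(module_forward(cfb, x, "deploy"), "fuse_module")
})

test_that("fusion is idempotent", {
  set.seed(26)
  blk <- cfb_block(6, 6, n = 1)
  invisible(module_forward(blk, array(rnorm(6 * 8 * 8), c(6, 8, 8, 1)), "train"))
  f1 <- fuse_module(blk)
  f2 <- fuse_module(f1)
  v1 <- lapply(collect_params(f1), function(p) p$v)
  v2 <- lapply(collect_params(f2), function(p) p$v)
  expect_identical(v1, v2)
})
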