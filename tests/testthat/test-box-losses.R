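# The IoU family and the scalar classification/regression losses.

test_that("iou handles identity, disjoint, partial overlap and degenerate boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  # symmetry
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), iou(c(1, 1, 3, 3), c(0, 0, 2, 2)))
  # both zero-area: 0 by convention
  expect_equal(iou(c(1, 1, 1, 1), c(1, 1, 1, 1)), 0)
})

test_that("giou adds the enclosing-box penalty and reduces to iou when nested", {
  expect_equal(giou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(giou(c(0, 0, 1, 1), c(2, 2, 3, 3)), -7 / 9)
  a <- c(0, 0, 4, 4); b <- c(1, 1, 2, 2)  # nested: enclosing box equals a
  expect_equal(giou(a, b), iou(a, b))
  # giou never exceeds iou
  set.seed(11)
  ba <- random_boxes(200); bb <- random_boxes(200)
  expect_true(all(giou(ba, bb) <= iou(ba, bb) + 1e-12))
})

test_that("eiou loss matches hand arithmetic and decreases along translation", {
  expect_equal(eiou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0)
  expect_equal(eiou_loss(c(0, 0, 2, 2), c(0, 0, 4, 4)), 1.3125)
  # translating a toward b strictly decreases the loss along the path
  target <- c(5, 5, 7, 7)
  shifts <- seq(0, 4, by = 0.5)
  vals <- sapply(shifts, function(s) eiou_loss(c(1 + s, 1 + s, 3 + s, 3 + s), target))
  expect_true(all(diff(vals) < 0))
})

test_that("siou angle term follows the sin^2 reading with its conventions", {
  # centers sharing y: no angular penalty
  t1 <- siou_terms(c(0, 0, 2, 2), c(4, 0, 6, 2))
  expect_equal(t1$lambda_angle, 0, tolerance = 1e-12)
  # 45-degree center offset: maximal angular term
  t2 <- siou_terms(c(0, 0, 2, 2), c(3, 3, 5, 5))
  expect_equal(t2$lambda_angle, 1, tolerance = 1e-12)
  # identical boxes: no distance, no shape penalty
  t3 <- siou_terms(c(0, 0, 2, 2), c(0, 0, 2, 2))
  expect_equal(t3$delta_dist, 0)
  expect_equal(t3$omega_shape, 0)
  expect_true(t3$lambda_angle == 0)  # coincident-center convention
})

test_that("siou loss reproduces the worked x-offset example and is translation invariant", {
  expect_equal(siou_loss(c(0, 0, 2, 2), c(2, 0, 4, 2)),
               1 + (1 - exp(-0.5)) / 2, tolerance = 1e-9)
  set.seed(12)
  a <- random_boxes(50); b <- random_boxes(50)
  sh <- cbind(3.7, -2.1, 3.7, -2.1)[rep(1, 50), ]
  expect_equal(siou_loss(a + sh, b + sh), siou_loss(a, b), tolerance = 1e-9)
  expect_true(all(siou_loss(a, b) >= 1 - iou(a, b) - 1e-12))
})

test_that("inner iou rescales about centers; ratio 1 is plain iou", {
  set.seed(13)
  a <- random_boxes(100); b <- random_boxes(100)
  expect_equal(inner_iou(a, b, 1), iou(a, b))
  # shrunken boxes that only touch at a corner
  expect_equal(inner_iou(c(0, 0, 2, 2), c(1, 1, 3, 3), 0.5), 0)
  # identical boxes keep iou 1 under any ratio
  expect_equal(inner_iou(c(0, 0, 2, 2), c(0, 0, 2, 2), 0.7), 1)
  expect_equal(inner_iou(c(0, 0, 2, 2), c(0, 0, 2, 2), 1.3), 1)
  expect_error(inner_iou(a, b, 0), "positive")
})

test_that("simiou matches the worked normalized example and its conventions", {
  a <- c(0, 0, 0.5, 0.5); b <- c(0.25, 0.25, 0.75, 0.75)
  expect_equal(simiou_loss(a, b), 1 - 1 / 7 + 0.125, tolerance = 1e-9)
  expect_equal(simiou_loss(a, a), 0)
  # theta sharpens the inner-overlap penalty
  l1 <- simiou_loss(a, b, loss_params(theta = 1))
  l2 <- simiou_loss(a, b, loss_params(theta = 2))
  inner <- inner_iou(a, b, 1)
  expect_gt(1 - inner^2, 1 - inner^1)
  # corner-norm variant differs only through the stated denominators
  lc <- simiou_loss(a, b, variant = "corner_norm")
  expect_equal(lc, 1 - 1 / 7 + (0.125 / 2 + 0.125), tolerance = 1e-9)
  expect_error(simiou_loss(c(0, 0, NA, 1), b), "finite")
})

test_that("simiou corner distances use image-extent normalization", {
  # same pair expressed in 100x100 pixels must equal the normalized value
  a <- c(0, 0, 50, 50); b <- c(25, 25, 75, 75)
  expect_equal(simiou_loss(a, b, img_w = 100, img_h = 100),
               simiou_loss(a / 100, b / 100))
})

test_that("box losses are invariant to joint translation and isotropic scaling", {
  set.seed(14)
  a <- random_boxes(40); b <- random_boxes(40)
  for (fn in list(function(x, y) giou_loss(x, y),
                  function(x, y) eiou_loss(x, y),
                  function(x, y) siou_loss(x, y))) {
    expect_equal(fn(a * 3, b * 3), fn(a, b), tolerance = 1e-8)
    sh <- matrix(rep(c(5, -2, 5, -2), each = 40), 40)
    expect_equal(fn(a + sh, b + sh), fn(a, b), tolerance = 1e-8)
  }
  # simiou after normalization: scaling box and image extent together
  expect_equal(simiou_loss(a * 2, b * 2, img_w = 20, img_h = 20),
               simiou_loss(a, b, img_w = 10, img_h = 10), tolerance = 1e-9)
})

test_that("every loss in the family is exactly zero on identical boxes", {
  set.seed(15)
  a <- random_boxes(100)
  expect_equal(giou_loss(a, a), rep(0, 100))
  expect_equal(eiou_loss(a, a), rep(0, 100))
  expect_equal(siou_loss(a, a), rep(0, 100))
  expect_equal(simiou_loss(a / 10, a / 10), rep(0, 100))
})

test_that("focal loss matches direct substitution and its limits", {
  expect_equal(focal_loss(1), 0)
  expect_equal(focal_loss(0.5, loss_params(focal_alpha = 0.25, focal_gamma = 2)),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  # gamma = 0, alpha -> 1 reduces toward plain cross-entropy
  p <- c(0.3, 0.6, 0.9)
  expect_equal(focal_loss(p, loss_params(focal_alpha = 1 - 1e-12, focal_gamma = 0)),
               -log(p), tolerance = 1e-6)
  expect_error(focal_loss(1.5), "0, 1")
})

test_that("elementwise losses follow their printed forms", {
  z <- elementwise_losses(c(0.2, 0.8), c(0.2, 0.8))
  expect_equal(unlist(z), c(mse = 0, l1 = 0, ce = -sum(c(0.2, 0.8) * log(c(0.2, 0.8))),
                            bce = unname(unlist(z)["bce"])))
  expect_equal(elementwise_losses(c(0, 2), c(1, 1))$mse, 1)
  expect_equal(elementwise_losses(1, 0.5)$bce, log(2), tolerance = 1e-9)
  expect_equal(elementwise_losses(c(1, 0), c(1, 0), eps = 1e-12)$bce, 0, tolerance = 1e-9)
  expect_error(elementwise_losses(1:3, 1:2), "length")
})

test_that("theta monotonicity: larger exponents intensify the inner penalty", {
  set.seed(16)
  for (i in 1:20) {
    a <- random_boxes(1, ext = 1)
    b <- random_boxes(1, ext = 1)
    inner <- inner_iou(a, b, 1)
    if (inner >= 1 || inner <= 0) next
    th <- sort(runif(2, 1, 4))
    expect_gt(1 - inner^th[2], 1 - inner^th[1])
  }
})

test_that("finite-difference box gradients descend the loss surface", {
  set.seed(17)
  for (nm in c("giou", "eiou", "siou", "simiou")) {
    fn <- box_loss_by_name(nm)
    a <- matrix(c(0.2, 0.2, 0.4, 0.45), 1)
    b <- matrix(c(0.5, 0.45, 0.8, 0.8), 1)
    g <- box_loss_grad(fn, a, b, loss_params())
    a2 <- a - 0.01 * g
    expect_lt(fn(a2, b, loss_params()), fn(a, b, loss_params()))
  }
})
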