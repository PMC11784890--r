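#' Tunable parameters of the loss family
#'
#' One container for every knob of the bounding-box and classification losses:
#' the power `theta` that sharpens the penalty on badly localized samples, the
#' inner-IoU rescaling ratio, the focal-loss class weight and focusing
#' exponent, the SIoU shape exponent, and the epsilon guard used in every
#' denominator.
#'
#' @param theta power applied to the inner-IoU and corner-distance terms of
#'   the composite loss; `>= 0`. Default 1 (no sharpening).
#' @param inner_ratio scale factor applied to both boxes about their centers
#'   before the overlap is measured; `1` reduces inner-IoU to plain IoU.
#'   Sensible range is about `[0.5, 1.5]`.
#' @param focal_alpha class-balance weight of the focal loss, in `(0, 1)`.
#' @param focal_gamma focusing exponent of the focal loss, `>= 0`.
#' @param shape_theta exponent of the SIoU shape term (conventionally 4).
#' @param eps small positive guard for denominators and logs.
#' @return a `loss_params` list.
#' @export
loss_params <- function(theta = 1, inner_ratio = 1, focal_alpha = 0.25,
                        focal_gamma = 2, shape_theta = 4, eps = 1e-9) {
  stopifnot(is.finite(theta), theta >= 0,
            is.finite(inner_ratio), inner_ratio > 0,
            is.finite(focal_alpha), focal_alpha > 0, focal_alpha < 1,
            is.finite(focal_gamma), focal_gamma >= 0,
            is.finite(shape_theta), shape_theta >= 0,
            is.finite(eps), eps > 0)
  structure(list(theta = theta, inner_ratio = inner_ratio,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 shape_theta = shape_theta, eps = eps),
            class = "loss_params")
}

# broadcast two box inputs to equal-length n x 4 matrices
pair_boxes <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
    else stop("box sets must have equal length (or one of length 1)")
  }
  list(a = a, b = b)
}

#' Intersection over union of paired boxes
#'
#' Overlap area divided by union area. By convention the IoU of two zero-area
#' boxes (and of any pair with zero union) is 0.
#'
#' @param a,b boxes in corner format: length-4 vectors or `n x 4` matrices,
#'   paired row by row.
#' @return numeric vector of values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  p <- pair_boxes(a, b); a <- p$a; b <- p$b
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  inter <- iw * ih
  uni <- box_area(a) + box_area(b) - inter
  unname(ifelse(uni > 0, inter / uni, 0))
}

#' Generalized IoU of paired boxes
#'
#' IoU minus the fraction of the smallest enclosing box not covered by the
#' union, so disjoint boxes are graded by how far apart they are. Ranges over
#' `(-1, 1]`; equals the IoU whenever the enclosing box coincides with the
#' union region (e.g. nested boxes). A degenerate enclosing box falls back to
#' the plain IoU.
#'
#' @inheritParams iou
#' @export
giou <- function(a, b) {
  p <- pair_boxes(a, b); a <- p$a; b <- p$b
  i <- iou(a, b)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  carea <- cw * ch
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  uni <- box_area(a) + box_area(b) - iw * ih
  unname(ifelse(carea > 0, i - (carea - uni) / carea, i))
}

#' @rdname giou
#' @export
giou_loss <- function(a, b) 1 - giou(a, b)

#' EIoU loss of paired boxes
#'
#' `1 - IoU` plus three squared-distance penalties, each normalized by the
#' matching dimension of the smallest enclosing box: center distance over the
#' squared enclosing diagonal, width difference over squared enclosing width,
#' height difference over squared enclosing height. Each penalty ratio lies in
#' `[0, 1]` and the loss is zero exactly for identical boxes.
#'
#' @inheritParams iou
#' @param eps guard for degenerate enclosing dimensions.
#' @export
eiou_loss <- function(a, b, eps = 1e-9) {
  p <- pair_boxes(a, b); a <- p$a; b <- p$b
  ca <- box_center(a); cb <- box_center(b)
  wa <- box_wh(a); wb <- box_wh(b)
  cw <- pmax(pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1]), eps)
  ch <- pmax(pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2]), eps)
  rho2 <- (ca[, 1] - cb[, 1])^2 + (ca[, 2] - cb[, 2])^2
  unname(1 - iou(a, b) + rho2 / (cw^2 + ch^2) +
    (wa[, 1] - wb[, 1])^2 / cw^2 + (wa[, 2] - wb[, 2])^2 / ch^2)
}

#' Intermediate terms of the SIoU loss
#'
#' Computes the angle, distance and shape components. The angle term
#' \eqn{\Lambda = 1 - 2\sin^2(\arcsin(c_h/\sigma) - \pi/4)} is built from the
#' center offset `c_h` along y and the center distance `sigma`; it is 1 when
#' the centers are offset at 45 degrees and 0 when they are axis-aligned. The
#' distance term \eqn{\Delta = \sum_{t=x,y}(1 - e^{-\gamma\rho_t})} uses
#' \eqn{\gamma = 2 - \Lambda} and squared center offsets normalized by the
#' enclosing-box extent; the shape term \eqn{\Omega} penalizes relative
#' width/height mismatch raised to `shape_theta`. Coincident centers
#' (`sigma < eps`) take the convention \eqn{\Lambda = 0}, \eqn{\rho_x =
#' \rho_y = 0} so that \eqn{\Delta = 0}.
#'
#' @inheritParams iou
#' @param params a [loss_params()] object (uses `shape_theta` and `eps`).
#' @return a list of numeric vectors: `lambda_angle`, `delta_dist`,
#'   `omega_shape`, `sigma_center`, `c_w`, `c_h` (enclosing-box extents),
#'   `rho_x`, `rho_y`, `gamma_dist`, `w_w`, `w_h`.
#' @export
siou_terms <- function(a, b, params = loss_params()) {
  p <- pair_boxes(a, b); a <- p$a; b <- p$b
  eps <- params$eps
  ca <- box_center(a); cb <- box_center(b)
  dx <- abs(cb[, 1] - ca[, 1]); dy <- abs(cb[, 2] - ca[, 2])
  sigma <- sqrt(dx^2 + dy^2)
  # enclosing-box extents normalize the center offsets in the distance term
  cw <- pmax(pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1]), eps)
  ch <- pmax(pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2]), eps)
  ok <- sigma >= eps
  sin_alpha <- ifelse(ok, pmin(dy / pmax(sigma, eps), 1), 0)
  lambda <- ifelse(ok, 1 - 2 * sin(asin(sin_alpha) - pi / 4)^2, 0)
  gamma <- 2 - lambda
  rho_x <- ifelse(ok, (dx / cw)^2, 0)
  rho_y <- ifelse(ok, (dy / ch)^2, 0)
  delta <- (1 - exp(-gamma * rho_x)) + (1 - exp(-gamma * rho_y))
  wa <- box_wh(a); wb <- box_wh(b)
  w_w <- abs(wa[, 1] - wb[, 1]) / pmax(pmax(wa[, 1], wb[, 1]), eps)
  w_h <- abs(wa[, 2] - wb[, 2]) / pmax(pmax(wa[, 2], wb[, 2]), eps)
  omega <- (1 - exp(-w_w))^params$shape_theta + (1 - exp(-w_h))^params$shape_theta
  lambda <- unname(lambda); delta <- unname(delta); omega <- unname(omega)
  list(lambda_angle = lambda, delta_dist = delta, omega_shape = omega,
       sigma_center = sigma, c_w = cw, c_h = ch,
       rho_x = rho_x, rho_y = rho_y, gamma_dist = gamma,
       w_w = w_w, w_h = w_h)
}

#' SIoU loss of paired boxes
#'
#' \eqn{1 - IoU + (\Delta + \Omega)/2} with the terms of [siou_terms()].
#' Zero exactly for identical boxes; always at least `1 - IoU`; invariant to
#' joint translation of both boxes.
#'
#' @inheritParams siou_terms
#' @export
siou_loss <- function(a, b, params = loss_params()) {
  t <- siou_terms(a, b, params)
  unname(1 - iou(a, b) + (t$delta_dist + t$omega_shape) / 2)
}

#' Inner IoU: overlap of center-rescaled boxes
#'
#' Both boxes are rescaled about their own centers by `ratio` before the
#' ordinary IoU is computed; `ratio = 1` reduces exactly to [iou()]. Ratios
#' below 1 sharpen the overlap signal for near-matching boxes, ratios above 1
#' soften it for distant ones.
#'
#' @inheritParams iou
#' @param ratio positive scale factor.
#' @export
inner_iou <- function(a, b, ratio = 1) {
  p <- pair_boxes(a, b)
  iou(box_rescale_about_center(p$a, ratio), box_rescale_about_center(p$b, ratio))
}

#' SIMIoU composite bounding-box loss
#'
#' The package's headline regression loss. Coordinates are first normalized by
#' the image extent so both height and width equal one; then
#' \deqn{L = 1 - \mathrm{inner}^{\theta} + (d_1/2 + d_2/2)^{\theta} +
#'   \tfrac12\,\alpha\,\gamma}
#' where `inner` is the inner-IoU of the pair, `d1`/`d2` are squared distances
#' between the upper-left and lower-right corners in normalized units,
#' `gamma` is the CIoU-style aspect-consistency term
#' \eqn{(4/\pi^2)(\arctan(w_b/h_b) - \arctan(w_a/h_a))^2} and
#' \eqn{\alpha = \gamma/((1 - IoU) + \gamma)} balances it (defined as 0 when
#' both numerator and denominator vanish, i.e. perfect match). The power
#' `theta` intensifies the penalty on badly localized samples. The
#' `"corner_norm"` variant divides the corner distances by \eqn{h^2 + w^2}
#' and \eqn{hw} instead of 2; after normalization both variants coincide up
#' to those constant denominators and the default `"canonical"` form is the
#' stated overall loss.
#'
#' @inheritParams iou
#' @param params a [loss_params()] object; `theta` and `inner_ratio` are used.
#' @param img_w,img_h image extent used to normalize coordinates. Use 1 if
#'   the boxes are already normalized.
#' @param variant `"canonical"` (corner distances halved) or `"corner_norm"`
#'   (corner distances divided by the squared diagonal and the area).
#' @return numeric vector of loss values, 0 for identical boxes.
#' @export
simiou_loss <- function(a, b, params = loss_params(), img_w = 1, img_h = 1,
                        variant = c("canonical", "corner_norm")) {
  variant <- match.arg(variant)
  p <- pair_boxes(a, b); a <- p$a; b <- p$b
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite box input")
  stopifnot(img_w > 0, img_h > 0)
  s <- diag(c(1 / img_w, 1 / img_h, 1 / img_w, 1 / img_h))
  an <- a %*% s; bn <- b %*% s
  inner <- inner_iou(an, bn, params$inner_ratio)
  d1 <- (an[, 1] - bn[, 1])^2 + (an[, 2] - bn[, 2])^2
  d2 <- (an[, 3] - bn[, 3])^2 + (an[, 4] - bn[, 4])^2
  eps <- params$eps
  wa <- box_wh(an); wb <- box_wh(bn)
  gam <- (4 / pi^2) *
    (atan(wb[, 1] / pmax(wb[, 2], eps)) - atan(wa[, 1] / pmax(wa[, 2], eps)))^2
  i <- iou(an, bn)
  den <- (1 - i) + gam
  alpha <- ifelse(den > eps, gam / den, 0)
  corner <- switch(variant,
    canonical   = d1 / 2 + d2 / 2,
    corner_norm = d1 / 2 + d2 / 1  # normalized image: h^2 + w^2 = 2, h*w = 1
  )
  unname(1 - inner^params$theta + corner^params$theta + 0.5 * alpha * gam)
}

#' Focal classification loss
#'
#' \eqn{-\alpha_t (1 - p_t)^{\gamma} \log(p_t)}: down-weights well-classified
#' samples so that rare, hard categories dominate the gradient. `p_t` is the
#' predicted probability of the true class; values are clamped to at least
#' `eps` before the log.
#'
#' @param p_t probability of the true class, in `(0, 1]` (vectorized).
#' @param params a [loss_params()] object (`focal_alpha`, `focal_gamma`, `eps`).
#' @export
focal_loss <- function(p_t, params = loss_params()) {
  if (any(!is.finite(p_t)) || any(p_t < 0) || any(p_t > 1))
    stop("p_t must lie in [0, 1]")
  p <- pmax(p_t, params$eps)
  -params$focal_alpha * (1 - p)^params$focal_gamma * log(p)
}

#' Elementwise regression and classification losses
#'
#' The four reference scalar losses: mean squared error, summed absolute
#' error (L1), cross entropy \eqn{-\sum p \log q}, and binary cross entropy
#' over predicted probabilities. `ce` treats `y_true` as the reference
#' distribution `p` and `y_pred` as the predicted `q`; `bce` treats `y_true`
#' as 0/1 labels and `y_pred` as probabilities.
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @param eps clamp for probabilities inside logs.
#' @return a list with elements `mse`, `l1`, `ce`, `bce` (all `>= 0`, all 0 at
#'   a perfect prediction).
#' @export
elementwise_losses <- function(y_true, y_pred, eps = 1e-12) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  q <- pmin(pmax(y_pred, eps), 1 - eps)
  list(
    mse = mean((y_true - y_pred)^2),
    l1 = sum(abs(y_true - y_pred)),
    ce = -sum(y_true * log(q)),
    bce = -sum(y_true * log(q) + (1 - y_true) * log(1 - q))
  )
}

#' Look up a box loss by name
#'
#' @param name one of `"giou"`, `"eiou"`, `"siou"`, `"simiou"`.
#' @return a function `f(a, b, params)` returning per-pair loss values (boxes
#'   in normalized coordinates for `"simiou"`).
#' @export
box_loss_by_name <- function(name) {
  switch(name,
    giou = function(a, b, params = loss_params()) giou_loss(a, b),
    eiou = function(a, b, params = loss_params()) eiou_loss(a, b, params$eps),
    siou = function(a, b, params = loss_params()) siou_loss(a, b, params),
    simiou = function(a, b, params = loss_params()) simiou_loss(a, b, params),
    stop("unknown loss '", name, "'; valid names: giou, eiou, siou, simiou")
  )
}

#' Numerical gradient of a box loss with respect to the first box
#'
#' Central finite differences on the four coordinates. The IoU-family losses
#' are piecewise smooth, so this is the workhorse for the gradient-descent
#' regression harness and for the matched-box term of the training objective.
#'
#' @param loss_fn a function `f(a, b, ...)` returning per-pair loss values.
#' @param a,b `n x 4` box matrices (paired rows).
#' @param ... passed through to `loss_fn`.
#' @param h step size.
#' @return an `n x 4` matrix of partial derivatives.
#' @export
box_loss_grad <- function(loss_fn, a, b, ..., h = 1e-5) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  g <- matrix(0, nrow(a), 4)
  for (j in 1:4) {
    ap <- a; am <- a
    ap[, j] <- ap[, j] + h
    am[, j] <- am[, j] - h
    g[, j] <- (loss_fn(ap, b, ...) - loss_fn(am, b, ...)) / (2 * h)
  }
  g
}
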