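# Shared fixtures and independent oracles used across the test files.

# random valid boxes inside [0, ext]^2
random_boxes <- function(n, ext = 10, min_side = 0.2) {
  x1 <- runif(n, 0, ext - min_side)
  y1 <- runif(n, 0, ext - min_side)
  w <- runif(n, min_side, ext / 2)
  h <- runif(n, min_side, ext / 2)
  cbind(x1, y1, pmin(x1 + w, ext), pmin(y1 + h, ext))
}

# Monte-Carlo point-membership oracle for IoU and GIoU: stratified jittered
# sampling over the smallest enclosing box of the pair. Independent of the
# closed-form area arithmetic in the package.
mc_iou_oracle <- function(a, b, k = 450L) {
  ex1 <- min(a[1], b[1]); ey1 <- min(a[2], b[2])
  ex2 <- max(a[3], b[3]); ey2 <- max(a[4], b[4])
  if (ex2 <= ex1 || ey2 <= ey1) return(list(iou = 0, giou = 0))
  gx <- (rep(seq_len(k), times = k) - runif(k * k)) / k
  gy <- (rep(seq_len(k), each = k) - runif(k * k)) / k
  px <- ex1 + gx * (ex2 - ex1)
  py <- ey1 + gy * (ey2 - ey1)
  in_a <- px >= a[1] & px <= a[3] & py >= a[2] & py <= a[4]
  in_b <- px >= b[1] & px <= b[3] & py >= b[2] & py <= b[4]
  p_union <- mean(in_a | in_b)
  p_inter <- mean(in_a & in_b)
  iou_mc <- if (p_union > 0) p_inter / p_union else 0
  list(iou = iou_mc, giou = iou_mc - (1 - p_union))
}

# Exhaustive, independently coded AP evaluator: for every rank prefix it
# redoes greedy matching from scratch and reads the 101-point area off the
# precision/recall points directly.
naive_greedy_match <- function(det_boxes, det_cls, gt_boxes, gt_cls, thr) {
  used <- rep(FALSE, nrow(gt_boxes))
  tp <- logical(nrow(det_boxes))
  for (i in seq_len(nrow(det_boxes))) {
    best <- 0; bestj <- 0
    for (j in seq_len(nrow(gt_boxes))) {
      if (used[j] || det_cls[i] != gt_cls[j]) next
      ix <- max(0, min(det_boxes[i, 3], gt_boxes[j, 3]) - max(det_boxes[i, 1], gt_boxes[j, 1]))
      iy <- max(0, min(det_boxes[i, 4], gt_boxes[j, 4]) - max(det_boxes[i, 2], gt_boxes[j, 2]))
      inter <- ix * iy
      ua <- (det_boxes[i, 3] - det_boxes[i, 1]) * (det_boxes[i, 4] - det_boxes[i, 2]) +
        (gt_boxes[j, 3] - gt_boxes[j, 1]) * (gt_boxes[j, 4] - gt_boxes[j, 2]) - inter
      ov <- if (ua > 0) inter / ua else 0
      if (ov >= thr && ov > best) { best <- ov; bestj <- j }
    }
    if (bestj > 0) { used[bestj] <- TRUE; tp[i] <- TRUE }
  }
  tp
}

naive_ap <- function(dets_by_image, gts_by_image, cls, thr) {
  recs <- list()
  n_gt <- 0L
  for (ii in seq_along(gts_by_image)) {
    g <- gts_by_image[[ii]]
    n_gt <- n_gt + sum(g$class_id == cls)
    d <- dets_by_image[[ii]]
    d <- d[d$class_id == cls, , drop = FALSE]
    if (nrow(d)) recs[[length(recs) + 1L]] <- cbind(img = ii, score = d$score,
                                                    as.matrix(d[, c("x1", "y1", "x2", "y2")]))
  }
  if (n_gt == 0) return(NA_real_)
  if (!length(recs)) return(0)
  all <- do.call(rbind, recs)
  all <- all[order(all[, "score"], decreasing = TRUE), , drop = FALSE]
  n <- nrow(all)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    tpk <- 0L
    for (ii in seq_along(gts_by_image)) {
      sel <- all[seq_len(k), , drop = FALSE]
      sel <- sel[sel[, "img"] == ii, , drop = FALSE]
      if (!nrow(sel)) next
      g <- gts_by_image[[ii]]
      g <- g[g$class_id == cls, , drop = FALSE]
      if (!nrow(g)) next
      tp <- naive_greedy_match(sel[, c("x1", "y1", "x2", "y2"), drop = FALSE],
                               rep(cls, nrow(sel)),
                               as.matrix(g[, c("x1", "y1", "x2", "y2")]),
                               g$class_id, thr)
      tpk <- tpk + sum(tp)
    }
    prec[k] <- tpk / k
    rec[k] <- tpk / n_gt
  }
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    ok <- which(rec >= r - 1e-12)
    ap <- ap + (if (length(ok)) max(prec[ok]) else 0)
  }
  ap / 101
}

# random detection / ground-truth scenario for metric tests
random_eval_case <- function(n_images = 3, n_classes = 3, ext = 100) {
  gts <- list(); dets <- list()
  for (i in seq_len(n_images)) {
    ng <- sample(0:6, 1)
    gb <- random_boxes(ng, ext, min_side = 5)
    gts[[i]] <- data.frame(x1 = gb[, 1], y1 = gb[, 2], x2 = gb[, 3], y2 = gb[, 4],
                           class_id = sample(n_classes, ng, replace = TRUE))
    nd <- sample(0:8, 1)
    # detections: a mix of jittered copies of gts and random noise
    rows <- list()
    for (k in seq_len(nd)) {
      if (ng > 0 && runif(1) < 0.6) {
        j <- sample(ng, 1)
        bb <- gb[j, ] + rnorm(4, sd = ext * 0.02)
        cc <- if (runif(1) < 0.85) gts[[i]]$class_id[j] else sample(n_classes, 1)
      } else {
        bb <- random_boxes(1, ext, min_side = 5)
        cc <- sample(n_classes, 1)
      }
      bb <- c(min(bb[1], bb[3]), min(bb[2], bb[4]), max(bb[1], bb[3]), max(bb[2], bb[4]))
      rows[[k]] <- data.frame(x1 = bb[1], y1 = bb[2], x2 = bb[3], y2 = bb[4],
                              class_id = cc, score = runif(1))
    }
    dets[[i]] <- if (nd > 0) do.call(rbind, rows) else
      data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
                 class_id = integer(), score = numeric())
  }
  list(dets = dets, gts = gts)
}

# compact two-class scene spec for training/prediction tests
smoke_scene_spec <- function() {
  scene_spec(img_size = 160L, grid_spacing = 72L, jitter = 0.2, occupancy = 0.9,
             class_probs = c(healthy = 0.5, dead = 0, grass = 0, yellow = 0,
                             small = 0.5),
             radius_range = c(12, 22), small_radius_range = c(6, 10),
             noise_sd = 0.01)
}

# 8-image 160x160 two-class training batch (the overfit fixture)
smoke_batch <- function(n_images = 8) {
  spec <- smoke_scene_spec()
  scenes <- lapply(seq_len(n_images), function(i) generate_scene(spec, seed = 100 + i))
  x <- array(0, c(3, 160, 160, n_images))
  targets <- vector("list", n_images)
  gts <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    xi <- aperm(scenes[[i]]$image, c(3, 1, 2))
    dim(xi) <- c(3, 160, 160, 1)
    x[, , , i] <- xi
    an <- scenes[[i]]$annotations
    b <- xywh_to_xyxy(as.matrix(an[, c("x", "y", "w", "h")]))
    cls <- ifelse(an$category_id == 1L, 1L, 2L)
    targets[[i]] <- list(boxes = b / 160, classes = cls)
    gts[[i]] <- data.frame(x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
                           class_id = cls)
  }
  list(x = x, targets = targets, scenes = scenes, gts = gts)
}
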