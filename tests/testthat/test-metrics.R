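# Detection evaluation: matching, precision/recall, AP, mAP, confusion matrix.

df_det <- function(boxes, cls, score) {
  b <- as.matrix(boxes)
  data.frame(x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
             class_id = cls, score = score)
}
df_gt <- function(boxes, cls) {
  b <- as.matrix(boxes)
  data.frame(x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4], class_id = cls)
}

test_that("greedy matching implements the TP rule with score order and gt consumption", {
  gt <- df_gt(matrix(c(0, 0, 10, 10), 1), 1)
  # IoU 0.4 below the 0.5 threshold -> FP
  d <- df_det(matrix(c(0, 0, 10, 4), 1), 1, 0.9)
  expect_equal(match_detections(d, gt, 0.5)$fp, 1)
  # two detections on one gt: higher score wins, the other is FP
  d2 <- df_det(rbind(c(0, 0, 10, 10), c(0.5, 0.5, 10, 10)), c(1, 1), c(0.4, 0.9))
  mr <- match_detections(d2, gt, 0.5)
  expect_equal(mr$tp, 1); expect_equal(mr$fp, 1)
  expect_true(mr$labels[2])  # the higher-score row
  # wrong class never matches
  d3 <- df_det(matrix(c(0, 0, 10, 10), 1), 2, 0.9)
  expect_equal(match_detections(d3, gt, 0.5)$tp, 0)
  # perfect one-to-one overlap
  gtm <- df_gt(rbind(c(0, 0, 5, 5), c(10, 10, 20, 20)), c(1, 2))
  dm <- df_det(rbind(c(0, 0, 5, 5), c(10, 10, 20, 20)), c(1, 2), c(0.9, 0.8))
  mm <- match_detections(dm, gtm, 0.5)
  expect_equal(c(mm$tp, mm$fp, mm$fn), c(2, 0, 0))
  # empty inputs give zero counts
  e <- match_detections(dm[0, ], gtm[0, ], 0.5)
  expect_equal(c(e$tp, e$fp, e$fn), c(0, 0, 0))
})

test_that("precision and recall follow their definitions with 0/0 -> 0", {
  expect_equal(precision_recall(list(tp = 8, fp = 2, fn = 0))[["precision"]], 0.8)
  expect_equal(precision_recall(list(tp = 8, fp = 0, fn = 2))[["recall"]], 0.8)
  expect_equal(unname(precision_recall(list(tp = 0, fp = 0, fn = 0))), c(0, 0))
})

test_that("average precision on hand-enumerable rankings", {
  gt <- df_gt(matrix(c(0, 0, 10, 10), 1), 1)
  # single matching detection -> AP 1
  expect_equal(average_precision(df_det(matrix(c(0, 0, 10, 10), 1), 1, 0.9), gt), 1)
  # no true positives -> AP 0
  expect_equal(average_precision(df_det(matrix(c(50, 50, 60, 60), 1), 1, 0.9), gt), 0)
  # ranked [FP, TP] over one gt: max precision 0.5 at every recall -> AP 0.5
  d <- df_det(rbind(c(50, 50, 60, 60), c(0, 0, 10, 10)), c(1, 1), c(0.9, 0.5))
  expect_equal(average_precision(d, gt), 0.5)
  # class without any gt instance is NA (excluded from means)
  expect_true(is.na(average_precision(d, gt, cls = 2)))
})

test_that("AP depends on score ranks only and behaves monotonically", {
  set.seed(41)
  repeat {
    case <- random_eval_case(n_images = 2)
    if (sum(sapply(case$gts, function(g) sum(g$class_id == 1))) > 0 &&
        sum(sapply(case$dets, function(d) sum(d$class_id == 1))) > 0) break
  }
  cls <- 1
  base <- average_precision(case$dets, case$gts, cls)
  rescaled <- lapply(case$dets, function(d) { d$score <- d$score * 7 + 1; d })
  expect_equal(average_precision(rescaled, case$gts, cls), base)
  # appending a lowest-ranked FP never increases AP
  worst <- lapply(case$dets, function(d) d)
  worst[[1]] <- rbind(worst[[1]],
                      df_det(matrix(c(900, 900, 910, 910), 1), cls, 1e-6))
  expect_lte(average_precision(worst, case$gts, cls), base + 1e-12)
  # covering a gt that no detection overlaps never decreases AP
  covered <- FALSE
  for (ii in seq_along(case$gts)) {
    g1 <- case$gts[[ii]]
    dcls <- case$dets[[ii]][case$dets[[ii]]$class_id == cls, , drop = FALSE]
    for (j in which(g1$class_id == cls)) {
      ious <- if (nrow(dcls)) box_iou_matrix(
        as.matrix(dcls[, c("x1", "y1", "x2", "y2")]),
        matrix(as.numeric(g1[j, c("x1", "y1", "x2", "y2")]), 1)) else 0
      if (max(ious) < 0.5) {
        better <- case$dets
        better[[ii]] <- rbind(better[[ii]],
                              df_det(g1[j, c("x1", "y1", "x2", "y2")], cls, 2))
        expect_gte(average_precision(better, case$gts, cls), base - 1e-12)
        covered <- TRUE
        break
      }
    }
    if (covered) break
  }
})

test_that("mean_ap aggregates classes and thresholds as stated", {
  thr <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(0.6, 2, 10)
  ap[2, ] <- 0.2
  mm <- mean_ap(ap, thr)
  expect_equal(mm$ap50, 0.4)
  expect_equal(mm$map, 0.4)
  # identical AP at all thresholds -> mAP equals that AP per class
  ap2 <- rbind(rep(1, 10), rep(0, 10))
  expect_equal(mean_ap(ap2, thr)$map, 0.5)
  # NA rows (no gt) are excluded
  ap3 <- rbind(rep(0.8, 10), NA)
  expect_equal(mean_ap(ap3, thr)$ap50, 0.8)
})

test_that("evaluator agrees with the independently coded exhaustive evaluator", {
  set.seed(42)
  worst <- 0
  for (trial in 1:20) {
    case <- random_eval_case(n_images = sample(1:3, 1), n_classes = 2)
    for (cls in 1:2) for (thr in c(0.5, 0.75)) {
      mine <- average_precision(case$dets, case$gts, cls, thr)
      ref <- naive_ap(case$dets, case$gts, cls, thr)
      if (is.na(mine) && is.na(ref)) next
      worst <- max(worst, abs(mine - ref))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("mAP equals the brute-force mean of the per-class/threshold AP table", {
  set.seed(43)
  case <- random_eval_case(n_images = 3, n_classes = 3)
  ev <- evaluate_detections(case$dets, case$gts, classes = 1:3)
  thr <- seq(0.5, 0.95, by = 0.05)
  tab <- matrix(NA_real_, 3, 10)
  for (c in 1:3) for (t in seq_along(thr))
    tab[c, t] <- average_precision(case$dets, case$gts, c, thr[t])
  expect_equal(ev$map, mean(tab[rowSums(!is.na(tab)) > 0, ], na.rm = TRUE))
})

test_that("confusion matrix cross-tabulates with background row/column", {
  gt <- df_gt(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), c(1, 2))
  # perfect predictions -> diagonal
  d <- df_det(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), c(1, 2), c(0.9, 0.9))
  cm <- confusion_matrix(d, gt, classes = 1:2)
  expect_equal(unname(diag(cm)), c(1, 1, 0))
  # class confusion recorded off-diagonal via class-agnostic matching
  d2 <- df_det(matrix(c(0, 0, 10, 10), 1), 2, 0.9)
  cm2 <- confusion_matrix(d2, gt, classes = 1:2)
  expect_equal(cm2[1, 2], 1L)        # actual 1 predicted 2
  expect_equal(cm2[2, 3], 1L)        # second gt missed -> background column
  # all detections below the score threshold -> all gts in background column
  d3 <- df_det(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)), c(1, 2), c(0.1, 0.2))
  cm3 <- confusion_matrix(d3, gt, score_threshold = 0.25, classes = 1:2)
  expect_equal(unname(cm3[1:2, 3]), c(1L, 1L))
  # conservation: row sums over true classes equal per-class gt counts
  set.seed(44)
  case <- random_eval_case(n_images = 3, n_classes = 3)
  cmr <- confusion_matrix(case$dets, case$gts, score_threshold = 0, classes = 1:3)
  gt_counts <- sapply(1:3, function(c)
    sum(sapply(case$gts, function(g) sum(g$class_id == c))))
  expect_equal(unname(rowSums(cmr)[1:3]), gt_counts)
})
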