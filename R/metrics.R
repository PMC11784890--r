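## COCO-style detection evaluation: greedy matching, precision/recall,
## 101-point interpolated AP, mAP over IoU 0.5:0.05:0.95, confusion matrix.

# detections / ground truth are data.frames with x1,y1,x2,y2,class_id and
# (detections only) score

#' Match detections against ground truth at one IoU threshold
#'
#' Greedy matching in decreasing score order: a detection is a true positive
#' iff it has the same class as, and IoU at least `iou_threshold` with, a
#' not-yet-matched ground-truth box (ties broken by highest IoU); every
#' ground-truth box can be consumed at most once. Unmatched ground truths are
#' false negatives.
#'
#' @param dets data.frame with `x1,y1,x2,y2,class_id,score`.
#' @param gts data.frame with `x1,y1,x2,y2,class_id`.
#' @param iou_threshold IoU threshold in (0,1).
#' @param class_agnostic ignore class labels when matching (used by the
#'   confusion matrix).
#' @return list with `labels` (logical per detection, TRUE = TP),
#'   `det_gt` (matched gt index per detection, NA if FP), `gt_matched`
#'   (logical per gt), and counts `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5,
                             class_agnostic = FALSE) {
  nd <- nrow(dets) %||% 0L
  ng <- nrow(gts) %||% 0L
  if (nd == 0 || ng == 0) {
    return(list(labels = logical(nd), det_gt = rep(NA_integer_, nd),
                gt_matched = logical(ng), tp = 0L, fp = nd, fn = ng))
  }
  ord <- order(dets$score, decreasing = TRUE)
  dboxes <- as.matrix(dets[ord, c("x1", "y1", "x2", "y2")])
  gboxes <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  im <- box_iou_matrix(dboxes, gboxes)
  gt_matched <- logical(ng)
  labels <- logical(nd)
  det_gt <- rep(NA_integer_, nd)
  for (k in seq_len(nd)) {
    cand <- which(!gt_matched & im[k, ] >= iou_threshold)
    if (!class_agnostic)
      cand <- cand[gts$class_id[cand] == dets$class_id[ord[k]]]
    if (length(cand)) {
      g <- cand[which.max(im[k, cand])]
      gt_matched[g] <- TRUE
      labels[ord[k]] <- TRUE
      det_gt[ord[k]] <- g
    }
  }
  list(labels = labels, det_gt = det_gt, gt_matched = gt_matched,
       tp = sum(labels), fp = sum(!labels), fn = sum(!gt_matched))
}

#' Precision and recall from match counts
#'
#' `TP/(TP+FP)` and `TP/(TP+FN)`, with the 0/0 case defined as 0.
#'
#' @param counts list with `tp`, `fp`, `fn` (e.g. from [match_detections()]).
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else 0
  r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else 0
  c(precision = p, recall = r)
}

# pooled TP flags and scores for one class over a list of images
pool_class_matches <- function(dets_by_image, gts_by_image, cls, iou_threshold) {
  scores <- numeric(0)
  tps <- logical(0)
  n_gt <- 0L
  for (i in seq_along(gts_by_image)) {
    d <- dets_by_image[[i]]
    g <- gts_by_image[[i]]
    d <- d[d$class_id == cls, , drop = FALSE]
    g <- g[g$class_id == cls, , drop = FALSE]
    n_gt <- n_gt + nrow(g)
    if (nrow(d) == 0) next
    mr <- match_detections(d, g, iou_threshold)
    scores <- c(scores, d$score)
    tps <- c(tps, mr$labels)
  }
  list(scores = scores, tp = tps, n_gt = n_gt)
}

#' Average precision at one IoU threshold
#'
#' Area under the precision-recall curve for one class, pooled over images.
#' The default follows the COCO convention: precision is made monotone
#' (maximum over recalls at least r) and averaged over the 101-point recall
#' grid 0, 0.01, ..., 1. `interpolation = "continuous"` integrates the
#' monotone curve exactly instead.
#'
#' @param dets_by_image,gts_by_image lists of per-image data.frames (see
#'   [match_detections()]); a single data.frame is treated as one image.
#' @param cls class id to evaluate.
#' @param iou_threshold IoU threshold.
#' @param interpolation `"101point"` or `"continuous"`.
#' @return AP in `[0,1]`, or `NA` if the class has no ground-truth instances.
#' @export
average_precision <- function(dets_by_image, gts_by_image, cls = 1L,
                              iou_threshold = 0.5,
                              interpolation = c("101point", "continuous")) {
  interpolation <- match.arg(interpolation)
  if (is.data.frame(dets_by_image)) dets_by_image <- list(dets_by_image)
  if (is.data.frame(gts_by_image)) gts_by_image <- list(gts_by_image)
  pool <- pool_class_matches(dets_by_image, gts_by_image, cls, iou_threshold)
  if (pool$n_gt == 0) return(NA_real_)
  if (length(pool$scores) == 0) return(0)
  ord <- order(pool$scores, decreasing = TRUE)
  tp <- cumsum(pool$tp[ord])
  fp <- cumsum(!pool$tp[ord])
  recall <- tp / pool$n_gt
  precision <- tp / (tp + fp)
  # monotone (right-to-left maximum) precision envelope
  penv <- rev(cummax(rev(precision)))
  if (interpolation == "101point") {
    grid <- seq(0, 1, by = 0.01)
    idx <- findInterval(grid, recall, left.open = TRUE) + 1L
    p_at <- ifelse(idx <= length(penv), penv[pmin(idx, length(penv))], 0)
    mean(p_at)
  } else {
    r <- c(0, recall)
    sum((r[-1] - r[-length(r)]) * penv)
  }
}

#' Summarize per-class AP into AP50 and mAP
#'
#' `AP50` is the mean over classes of the AP at IoU 0.5; `mAP` is the mean
#' over classes and the ten thresholds 0.5:0.05:0.95. Classes with no
#' ground-truth instances (NA rows) are excluded from both means.
#'
#' @param per_class_ap matrix of APs, classes in rows, thresholds in columns.
#' @param thresholds the IoU thresholds labelling the columns.
#' @return list with `ap50` and `map`.
#' @export
mean_ap <- function(per_class_ap, thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(ncol(per_class_ap) == length(thresholds))
  valid <- rowSums(!is.na(per_class_ap)) > 0
  if (!any(valid)) stop("no class has ground-truth instances")
  i50 <- which(abs(thresholds - 0.5) < 1e-9)
  list(ap50 = mean(per_class_ap[valid, i50]),
       map = mean(per_class_ap[valid, , drop = FALSE], na.rm = TRUE))
}

#' Full COCO-style evaluation
#'
#' Per-class AP at IoU 0.5:0.05:0.95, AP50, mAP, dataset precision/recall at
#' IoU 0.5 over all supplied detections, and the confusion matrix.
#'
#' @param dets_by_image,gts_by_image lists of per-image data.frames.
#' @param classes integer vector of class ids to evaluate.
#' @param thresholds IoU thresholds.
#' @param interpolation AP interpolation rule (see [average_precision()]).
#' @return an `eval_result` list.
#' @export
evaluate_detections <- function(dets_by_image, gts_by_image,
                                classes = NULL,
                                thresholds = seq(0.5, 0.95, by = 0.05),
                                interpolation = "101point") {
  if (is.null(classes)) {
    classes <- sort(unique(c(
      unlist(lapply(gts_by_image, function(g) g$class_id)),
      unlist(lapply(dets_by_image, function(d) d$class_id)))))
  }
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(classes, thresholds))
  for (ci in seq_along(classes)) for (ti in seq_along(thresholds)) {
    ap[ci, ti] <- average_precision(dets_by_image, gts_by_image, classes[ci],
                                    thresholds[ti], interpolation)
  }
  counts <- list(tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(gts_by_image)) {
    mr <- match_detections(dets_by_image[[i]], gts_by_image[[i]], 0.5)
    counts$tp <- counts$tp + mr$tp
    counts$fp <- counts$fp + mr$fp
    counts$fn <- counts$fn + mr$fn
  }
  pr <- precision_recall(counts)
  mm <- mean_ap(ap, thresholds)
  structure(list(per_class_ap = ap, ap50 = mm$ap50, map = mm$map,
                 precision = pr[["precision"]], recall = pr[["recall"]],
                 confusion = confusion_matrix(dets_by_image, gts_by_image,
                                              classes = classes)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AP50 %.4f | mAP(0.5:0.95) %.4f | precision %.4f | recall %.4f\n",
              x$ap50, x$map, x$precision, x$recall))
  cat("per-class AP50:\n")
  print(round(x$per_class_ap[, 1], 4))
  invisible(x)
}

#' Detection confusion matrix
#'
#' Class-agnostic greedy IoU matching (detections above `score_threshold`,
#' in score order) followed by cross-tabulation of true vs predicted class.
#' Rows are actual categories, columns predicted; the extra `background` row
#' collects unmatched detections (false alarms) and the `background` column
#' collects missed ground truths.
#'
#' @param dets_by_image,gts_by_image lists of per-image data.frames.
#' @param iou_threshold,score_threshold matching and score cut-offs in (0,1).
#' @param classes class ids defining the matrix order.
#' @return an `(m+1) x (m+1)` integer matrix of counts.
#' @export
confusion_matrix <- function(dets_by_image, gts_by_image,
                             iou_threshold = 0.5, score_threshold = 0.25,
                             classes = NULL) {
  if (is.data.frame(dets_by_image)) dets_by_image <- list(dets_by_image)
  if (is.data.frame(gts_by_image)) gts_by_image <- list(gts_by_image)
  if (is.null(classes)) {
    classes <- sort(unique(c(
      unlist(lapply(gts_by_image, function(g) g$class_id)),
      unlist(lapply(dets_by_image, function(d) d$class_id)))))
  }
  m <- length(classes)
  cm <- matrix(0L, m + 1L, m + 1L,
               dimnames = list(actual = c(classes, "background"),
                               predicted = c(classes, "background")))
  for (i in seq_along(gts_by_image)) {
    d <- dets_by_image[[i]]
    d <- d[d$score >= score_threshold, , drop = FALSE]
    g <- gts_by_image[[i]]
    mr <- match_detections(d, g, iou_threshold, class_agnostic = TRUE)
    for (k in seq_len(nrow(d))) {
      pc <- match(d$class_id[k], classes)
      if (!is.na(mr$det_gt[k])) {
        ac <- match(g$class_id[mr$det_gt[k]], classes)
        cm[ac, pc] <- cm[ac, pc] + 1L
      } else {
        cm[m + 1L, pc] <- cm[m + 1L, pc] + 1L
      }
    }
    missed <- which(!mr$gt_matched)
    for (gidx in missed) {
      ac <- match(g$class_id[gidx], classes)
      cm[ac, m + 1L] <- cm[ac, m + 1L] + 1L
    }
  }
  cm
}
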