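#' Solve the rectangular linear assignment problem
#'
#' Jonker-Volgenant shortest-augmenting-path algorithm (O(n^2 m)) minimizing
#' total cost, with rows <= columns. Every row is assigned to exactly one
#' distinct column.
#'
#' @param cost numeric `n x m` matrix, `n <= m`, finite entries.
#' @return integer vector of length `n`: the column assigned to each row.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  if (n > m) stop("assignment needs rows <= columns")
  if (any(!is.finite(cost))) stop("assignment cost must be finite")
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)   # row currently assigned to each column (0 = free)
  way <- integer(m)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) out[p[j]] <- j
  out
}

#' One-to-one matching of queries to ground-truth objects
#'
#' Builds the DETR-style matching cost -- a class term (negative predicted
#' probability of the true class), an L1 term on center-size box coordinates
#' and a GIoU term -- and solves the assignment so each ground-truth object is
#' matched to exactly one query; all other queries are negatives.
#'
#' @param scores `Q x nc` matrix of per-class probabilities.
#' @param boxes `Q x 4` predicted boxes, corner format, normalized to `[0,1]`.
#' @param gt_boxes `G x 4` ground-truth boxes, corner format, normalized.
#' @param gt_classes integer vector of length `G` (1-based class ids).
#' @param w_cls,w_l1,w_iou cost-term weights.
#' @return integer vector of length `G`: matched query index per object
#'   (empty for empty ground truth).
#' @export
hungarian_match <- function(scores, boxes, gt_boxes, gt_classes,
                            w_cls = 2, w_l1 = 5, w_iou = 2) {
  gt_boxes <- as_box_matrix(gt_boxes)
  G <- nrow(gt_boxes)
  if (G == 0) return(integer(0))
  if (G > nrow(boxes)) stop("more ground-truth objects than queries")
  ccls <- -t(scores[, gt_classes, drop = FALSE])          # G x Q
  pc <- xyxy_to_cxcywh(boxes)
  gc <- xyxy_to_cxcywh(gt_boxes)
  cl1 <- matrix(0, G, nrow(boxes))
  for (k in 1:4) cl1 <- cl1 + abs(outer(gc[, k], pc[, k], "-"))
  cg <- matrix(0, G, nrow(boxes))
  for (g in seq_len(G)) {
    cg[g, ] <- 1 - giou(boxes, gt_boxes[rep(g, nrow(boxes)), , drop = FALSE])
  }
  cost <- w_cls * ccls + w_l1 * cl1 + w_iou * cg
  solve_assignment(cost)
}
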