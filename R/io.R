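## Image and annotation I/O, preprocessing, run configuration.

# bilinear resize of an H x W x C array (pixel centers at half-integers)
resize_bilinear <- function(img, nh, nw) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  sy <- (seq_len(nh) - 0.5) * h / nh + 0.5
  sx <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h); wy <- pmin(pmax(sy - y0, 0), 1)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(nh, nw, nc))
  for (c in seq_len(nc)) {
    m <- img[, , c]
    a <- m[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
      m[y0, x1, drop = FALSE] * outer(1 - wy, wx) +
      m[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
      m[y1, x1, drop = FALSE] * outer(wy, wx)
    out[, , c] <- a
  }
  out
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize followed by symmetric gray padding to
#' `target x target`. The returned transform maps box coordinates into and
#' out of the letterboxed frame exactly (affine, invertible to within
#' rounding of the resize).
#'
#' @param image numeric array `H x W x 3`, values in `[0, 1]`.
#' @param target output side length (default 640).
#' @param pad_value fill value for the padded border (gray 114/255).
#' @return list with `image` (target x target x 3), `scale`, `pad_x`,
#'   `pad_y`, `orig_w`, `orig_h`.
#' @export
letterbox <- function(image, target = 640L, pad_value = 114 / 255) {
  d <- dim(image)
  if (length(d) != 3 || d[1] == 0 || d[2] == 0) stop("letterbox: empty or non-RGB image")
  h <- d[1]; w <- d[2]
  s <- min(target / h, target / w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  resized <- if (nh == h && nw == w) image else resize_bilinear(image, nh, nw)
  out <- array(pad_value, c(target, target, d[3]))
  py <- (target - nh) %/% 2L
  px <- (target - nw) %/% 2L
  out[py + seq_len(nh), px + seq_len(nw), ] <- resized
  list(image = out, scale = s, pad_x = px, pad_y = py, orig_w = w, orig_h = h)
}

#' @rdname letterbox
#' @param boxes corner-format box matrix in original image pixels.
#' @param lb a letterbox transform.
#' @export
letterbox_boxes <- function(boxes, lb) {
  b <- as_box_matrix(boxes)
  cbind(b[, 1] * lb$scale + lb$pad_x, b[, 2] * lb$scale + lb$pad_y,
        b[, 3] * lb$scale + lb$pad_x, b[, 4] * lb$scale + lb$pad_y)
}

#' @rdname letterbox
#' @export
letterbox_invert <- function(boxes, lb) {
  b <- as_box_matrix(boxes)
  cbind((b[, 1] - lb$pad_x) / lb$scale, (b[, 2] - lb$pad_y) / lb$scale,
        (b[, 3] - lb$pad_x) / lb$scale, (b[, 4] - lb$pad_y) / lb$scale)
}

## ---- COCO JSON --------------------------------------------------------------

need_field <- function(x, field, where) {
  if (is.null(x[[field]])) stop("malformed COCO JSON: missing '", field, "' in ", where)
  x[[field]]
}

#' Read a COCO detection dataset
#'
#' Parses `images`, `annotations` and `categories` into data.frames. Boxes
#' are the on-disk `xywh` convention, 0-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return list with data.frames `images` (`id, file_name, width, height`),
#'   `annotations` (`id, image_id, category_id, x, y, w, h, area, iscrowd`,
#'   and `score` if present) and `categories` (`id, name`).
#' @export
read_coco <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("images", "annotations", "categories"))
    if (is.null(js[[f]])) stop("malformed COCO JSON: missing '", f, "'")
  images <- do.call(rbind, lapply(js$images, function(im) {
    data.frame(id = need_field(im, "id", "images"),
               file_name = need_field(im, "file_name", "images"),
               width = need_field(im, "width", "images"),
               height = need_field(im, "height", "images"),
               stringsAsFactors = FALSE)
  })) %||% data.frame(id = integer(), file_name = character(),
                      width = integer(), height = integer())
  annotations <- do.call(rbind, lapply(js$annotations, function(an) {
    bb <- need_field(an, "bbox", "annotations")
    if (length(bb) != 4) stop("malformed COCO JSON: 'bbox' must have 4 values")
    data.frame(id = need_field(an, "id", "annotations"),
               image_id = need_field(an, "image_id", "annotations"),
               category_id = need_field(an, "category_id", "annotations"),
               x = bb[[1]], y = bb[[2]], w = bb[[3]], h = bb[[4]],
               area = an$area %||% (bb[[3]] * bb[[4]]),
               iscrowd = an$iscrowd %||% 0L,
               score = an$score %||% NA_real_)
  })) %||% data.frame(id = integer(), image_id = integer(),
                      category_id = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), area = numeric(),
                      iscrowd = integer(), score = numeric())
  categories <- do.call(rbind, lapply(js$categories, function(ct) {
    data.frame(id = need_field(ct, "id", "categories"),
               name = need_field(ct, "name", "categories"),
               stringsAsFactors = FALSE)
  })) %||% data.frame(id = integer(), name = character())
  list(images = images, annotations = annotations, categories = categories)
}

#' @rdname read_coco
#' @param ds a dataset list as returned by `read_coco()`.
#' @export
write_coco <- function(ds, path) {
  images <- lapply(seq_len(nrow(ds$images)), function(i) {
    im <- ds$images[i, ]
    list(id = im$id, file_name = im$file_name, width = im$width, height = im$height)
  })
  annotations <- lapply(seq_len(nrow(ds$annotations)), function(i) {
    an <- ds$annotations[i, ]
    out <- list(id = an$id, image_id = an$image_id,
                category_id = an$category_id,
                bbox = c(an$x, an$y, an$w, an$h),
                area = an$area, iscrowd = an$iscrowd)
    if (!is.na(an$score)) out$score <- an$score
    out
  })
  categories <- lapply(seq_len(nrow(ds$categories)), function(i) {
    ct <- ds$categories[i, ]
    list(id = ct$id, name = ct$name)
  })
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = categories),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- YOLO txt ---------------------------------------------------------------

#' Write annotations as YOLO txt files
#'
#' One `.txt` per image (named after the image file stem), each line
#' `class cx cy w h` with 0-based class ids and coordinates normalized by the
#' image size and clamped to `[0, 1]`.
#'
#' @param ds a COCO dataset list (see [read_coco()]).
#' @param dir output directory (created if needed).
#' @export
write_yolo_txt <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catmap <- match(ds$annotations$category_id, ds$categories$id)
  for (i in seq_len(nrow(ds$images))) {
    im <- ds$images[i, ]
    stem <- sub("\\.[^.]+$", "", im$file_name)
    an <- ds$annotations[ds$annotations$image_id == im$id, , drop = FALSE]
    ci <- catmap[ds$annotations$image_id == im$id]
    lines <- character(0)
    if (nrow(an) > 0) {
      cx <- pmin(pmax((an$x + an$w / 2) / im$width, 0), 1)
      cy <- pmin(pmax((an$y + an$h / 2) / im$height, 0), 1)
      ww <- pmin(pmax(an$w / im$width, 0), 1)
      hh <- pmin(pmax(an$h / im$height, 0), 1)
      lines <- sprintf("%d %.8f %.8f %.8f %.8f", ci - 1L, cx, cy, ww, hh)
    }
    writeLines(lines, file.path(dir, paste0(stem, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_yolo_txt
#' @param images,categories data.frames giving image sizes/names and category
#'   ids, as in a COCO dataset (YOLO txt itself stores neither).
#' @return a COCO dataset list.
#' @export
read_yolo_txt <- function(dir, images, categories) {
  anns <- list()
  aid <- 0L
  for (i in seq_len(nrow(images))) {
    im <- images[i, ]
    stem <- sub("\\.[^.]+$", "", im$file_name)
    f <- file.path(dir, paste0(stem, ".txt"))
    if (!file.exists(f)) next
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(v) != 5) stop("malformed YOLO line: '", ln, "'")
      cls <- as.integer(v[1])
      if (cls < 0 || cls >= nrow(categories))
        stop("YOLO class id ", cls, " out of range [0, ", nrow(categories) - 1, "]")
      cx <- pmin(pmax(v[2], 0), 1); cy <- pmin(pmax(v[3], 0), 1)
      ww <- pmin(pmax(v[4], 0), 1); hh <- pmin(pmax(v[5], 0), 1)
      aid <- aid + 1L
      anns[[aid]] <- data.frame(
        id = aid, image_id = im$id, category_id = categories$id[cls + 1L],
        x = (cx - ww / 2) * im$width, y = (cy - hh / 2) * im$height,
        w = ww * im$width, h = hh * im$height,
        area = ww * im$width * hh * im$height, iscrowd = 0L, score = NA_real_)
    }
  }
  annotations <- if (length(anns)) do.call(rbind, anns) else
    data.frame(id = integer(), image_id = integer(), category_id = integer(),
               x = numeric(), y = numeric(), w = numeric(), h = numeric(),
               area = numeric(), iscrowd = integer(), score = numeric())
  list(images = images, annotations = annotations, categories = categories)
}

## ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' Training hyperparameters mirroring the study setup: learning rate 1e-4,
#' weight decay 1e-4, 2000 warm-up iterations, batch size 4, 640x640 input,
#' seed 0, SIMIoU regression loss.
#'
#' @export
default_run_config <- function() {
  list(scale = "l", nc = 5L, cfb = TRUE, lfpn = TRUE,
       loss = "simiou", theta = 1, inner_ratio = 1,
       lr = 1e-4, weight_decay = 1e-4, warmup = 2000L, epochs = 300L,
       batch_size = 4L, img_size = 640L, n_queries = 300L, seed = 0L)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(base, cfg)
  if (!out$loss %in% c("giou", "eiou", "siou", "simiou"))
    stop("loss must be one of giou, eiou, siou, simiou")
  out
}

## ---- loss convergence simulation --------------------------------------------

#' Gradient-descent box-regression harness for comparing losses
#'
#' For each trial, a random initial box is regressed onto a random target box
#' by gradient descent on the chosen loss (finite-difference gradients on the
#' four corner coordinates, boxes in the normalized unit frame). The descent
#' uses adaptive per-coordinate step scaling (Adam-style moments) with base
#' step `step_size`, since the IoU-family losses have gradient magnitudes
#' that vary by orders of magnitude between the disjoint and the near-match
#' regimes. Reports, per loss, the median number of steps until IoU with the
#' target reaches `iou_target` (trials that never reach it count as `steps`),
#' the mean final IoU, the mean final loss, and the failure rate. The same
#' seeded box pairs are used for every loss, and all trials step in parallel.
#'
#' @param losses character vector of loss names.
#' @param n_trials number of random box pairs.
#' @param steps maximum gradient steps per trial.
#' @param step_size base step size of the adaptive descent.
#' @param seed RNG seed for the box pairs.
#' @param params a [loss_params()] shared by all losses.
#' @param iou_target success threshold.
#' @return data.frame with one row per loss.
#' @export
loss_convergence_sim <- function(losses = c("giou", "eiou", "siou", "simiou"),
                                 n_trials = 100L, steps = 200L,
                                 step_size = 0.05, seed = 0L,
                                 params = loss_params(), iou_target = 0.99) {
  fns <- lapply(losses, box_loss_by_name)  # errors early on unknown names
  init <- with_seed(seed, {
    tc <- matrix(runif(2 * n_trials, 0.35, 0.65), n_trials)
    tw <- matrix(runif(2 * n_trials, 0.2, 0.4), n_trials)
    ic <- matrix(runif(2 * n_trials, 0.1, 0.9), n_trials)
    iw <- matrix(runif(2 * n_trials, 0.1, 0.5), n_trials)
    list(target = cbind(tc - tw / 2, tc + tw / 2),
         init = cbind(ic - iw / 2, ic + iw / 2))
  })
  res <- lapply(seq_along(losses), function(li) {
    fn <- fns[[li]]
    b <- init$init
    tg <- init$target
    steps_taken <- rep(as.integer(steps), n_trials)
    m1 <- b * 0; m2 <- b * 0
    for (k in seq_len(steps)) {
      done <- steps_taken < k | iou(b, tg) >= iou_target
      steps_taken[done & steps_taken == steps] <-
        pmin(steps_taken[done & steps_taken == steps], k - 1L)
      if (all(done)) break
      gr <- box_loss_grad(fn, b, tg, params)
      gr[done, ] <- 0
      m1 <- 0.9 * m1 + 0.1 * gr
      m2 <- 0.999 * m2 + 0.001 * gr^2
      # harmonic step decay: constant steps orbit the optimum at radius
      # ~step_size and never reach the tight IoU target
      upd <- (step_size / (1 + 0.1 * k)) *
        (m1 / (1 - 0.9^k)) / (sqrt(m2 / (1 - 0.999^k)) + 1e-8)
      upd[done, ] <- 0  # converged trials stay frozen
      b <- b - upd
      # keep rectangles valid (minimum-extent guard)
      bad <- b[, 3] < b[, 1] + 1e-4
      mid <- (b[, 1] + b[, 3]) / 2
      b[bad, 1] <- mid[bad] - 5e-5; b[bad, 3] <- mid[bad] + 5e-5
      bad <- b[, 4] < b[, 2] + 1e-4
      mid <- (b[, 2] + b[, 4]) / 2
      b[bad, 2] <- mid[bad] - 5e-5; b[bad, 4] <- mid[bad] + 5e-5
    }
    fi <- iou(b, tg)
    data.frame(loss = losses[li],
               median_steps = stats::median(steps_taken),
               mean_final_iou = mean(fi),
               mean_final_loss = mean(fn(b, tg, params)),
               fail_rate = mean(fi < iou_target))
  })
  do.call(rbind, res)
}
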