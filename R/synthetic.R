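## Deterministic synthetic overhead plantation scenes with COCO annotations.
## Emulates the statistics of UAV oil-palm surveys: five growth-status
## classes with extreme imbalance, a dense jittered planting grid, many
## targets smaller than 32x32 px, illumination gradients and sensor noise.

palm_classes <- function() c("healthy", "dead", "grass", "yellow", "small")

# per-class instance counts of the reference survey (training split)
train_class_counts <- c(healthy = 201303, dead = 599, grass = 953,
                        yellow = 3103, small = 56893)
val_class_counts <- c(healthy = 24884, dead = 61, grass = 95,
                      yellow = 411, small = 7395)

#' Synthetic plantation scene specification
#'
#' Generative parameters of one overhead scene: image size, planting-grid
#' geometry, class frequencies, canopy radius distributions (with a
#' sub-16-px-radius mode so a large fraction of boxes fall below 32x32 px),
#' illumination gradient and sensor noise.
#'
#' @param img_size square image side in pixels.
#' @param grid_spacing planting-grid pitch in pixels.
#' @param jitter plant-center jitter as a fraction of the grid pitch.
#' @param occupancy probability that a grid cell holds a plant.
#' @param class_probs named probabilities over the five classes (sum to 1).
#' @param radius_range radius range (px) of full-grown canopies; `small`
#'   plants use `small_radius_range`.
#' @param small_radius_range radius range of the `small` class.
#' @param illum_amp amplitude of the linear illumination gradient.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(img_size = 320L, grid_spacing = 36L, jitter = 0.25,
                       occupancy = 0.85,
                       class_probs = train_class_counts / sum(train_class_counts),
                       radius_range = c(9, 24),
                       small_radius_range = c(5, 10),
                       illum_amp = 0.25, noise_sd = 0.02) {
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class probabilities must sum to 1")
  if (!identical(sort(names(class_probs)), sort(palm_classes())))
    stop("class_probs must be named with: ", paste(palm_classes(), collapse = ", "))
  if (grid_spacing < 8) stop("grid too dense: spacing must be at least 8 px")
  if (grid_spacing > img_size) stop("grid spacing exceeds image size")
  structure(list(img_size = as.integer(img_size),
                 grid_spacing = as.integer(grid_spacing), jitter = jitter,
                 occupancy = occupancy,
                 class_probs = class_probs[palm_classes()],
                 radius_range = radius_range,
                 small_radius_range = small_radius_range,
                 illum_amp = illum_amp, noise_sd = noise_sd),
            class = "scene_spec")
}

#' Default scene specification
#'
#' Class probabilities proportional to the reference survey's training-split
#' instance counts (healthy 201303, dead 599, grass 953, yellow 3103, small
#' 56893 of 262811 total): healthy about 0.766, small 0.216, yellow 0.0118,
#' grass 0.0036, dead 0.0023.
#'
#' @param split `"train"` or `"val"`: which split's class frequencies to use.
#' @export
default_spec <- function(split = c("train", "val")) {
  split <- match.arg(split)
  counts <- if (split == "train") train_class_counts else val_class_counts
  scene_spec(class_probs = counts / sum(counts))
}

# class-conditioned canopy base colors (RGB in [0,1])
class_palette <- function() {
  rbind(healthy = c(0.13, 0.42, 0.15),
        dead = c(0.45, 0.36, 0.25),
        grass = c(0.45, 0.55, 0.20),
        yellow = c(0.72, 0.68, 0.18),
        small = c(0.25, 0.60, 0.28))
}

#' Render one synthetic plantation scene
#'
#' Lays out a jittered planting grid, samples a class and canopy radius per
#' occupied cell, renders textured canopy discs over a soil background,
#' applies an illumination gradient in a random direction, quantizes to
#' 8-bit RGB, and adds sensor noise. Each plant yields one tight bounding box
#' computed from the actually rendered extent (clipped to the image). Output
#' is a pure function of `(spec, seed)`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @return list with `image` (`img_size x img_size x 3`, values in `[0,1]`,
#'   8-bit quantized) and `annotations` (data.frame `x, y, w, h`
#'   (COCO xywh, 0-based), `category_id` (1..5), `class` name).
#' @export
generate_scene <- function(spec = default_spec(), seed = 0L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    s <- spec$img_size
    # soil background with low-frequency mottling
    base <- c(0.35, 0.27, 0.19)
    coarse <- array(stats::runif(3 * 8 * 8, -0.05, 0.05), c(8, 8, 3))
    bgtex <- resize_bilinear(coarse, s, s)
    img <- array(rep(base, each = s * s), c(s, s, 3)) + bgtex
    centers <- seq(spec$grid_spacing %/% 2L, s, by = spec$grid_spacing)
    anns <- list()
    k <- 0L
    pal <- class_palette()
    cls_names <- palm_classes()
    for (gy in centers) for (gx in centers) {
      if (stats::runif(1) > spec$occupancy) next
      cls <- sample.int(5L, 1L, prob = spec$class_probs)
      r <- if (cls_names[cls] == "small")
        stats::runif(1, spec$small_radius_range[1], spec$small_radius_range[2])
      else
        stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      cx <- gx + stats::runif(1, -1, 1) * spec$jitter * spec$grid_spacing
      cy <- gy + stats::runif(1, -1, 1) * spec$jitter * spec$grid_spacing
      ys <- max(1L, floor(cy - r)):min(s, ceiling(cy + r))
      xs <- max(1L, floor(cx - r)):min(s, ceiling(cx + r))
      if (length(ys) < 2 || length(xs) < 2) next
      dy <- outer(ys - cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - cx)
      dist <- sqrt(dy^2 + dx^2)
      # grass patches are ragged; canopies are near-circular
      edge <- if (cls_names[cls] == "grass")
        r * (0.7 + 0.3 * stats::runif(length(dist)))
      else r
      mask <- dist <= edge
      if (!any(mask)) next
      falloff <- pmax(0, 1 - (dist / r)^2)
      tex <- 1 + stats::rnorm(length(dist), sd = 0.08)
      col <- pal[cls, ]
      for (ch in 1:3) {
        tile <- img[ys, xs, ch]
        plant <- col[ch] * (0.65 + 0.35 * falloff) * tex
        tile[mask] <- plant[mask]
        img[ys, xs, ch] <- tile
      }
      # tight box of the rendered extent
      rows <- range(which(apply(mask, 1, any)))
      colsr <- range(which(apply(mask, 2, any)))
      x1 <- xs[colsr[1]] - 1L; x2 <- xs[colsr[2]]
      y1 <- ys[rows[1]] - 1L; y2 <- ys[rows[2]]
      k <- k + 1L
      anns[[k]] <- data.frame(x = x1, y = y1, w = x2 - x1, h = y2 - y1,
                              category_id = cls, class = cls_names[cls],
                              stringsAsFactors = FALSE)
    }
    # illumination gradient along a random direction
    theta <- stats::runif(1, 0, 2 * pi)
    gx <- outer(rep(1, s), (seq_len(s) - s / 2) / s)
    gyr <- outer((seq_len(s) - s / 2) / s, rep(1, s))
    grad <- 1 + spec$illum_amp * (cos(theta) * gx + sin(theta) * gyr)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255  # 8-bit quantization
    noise <- array(stats::rnorm(length(img), sd = spec$noise_sd), dim(img))
    img <- pmin(pmax(img + noise, 0), 1)
    img <- round(img * 255) / 255
    annotations <- if (k > 0) do.call(rbind, anns) else
      data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                 category_id = integer(), class = character())
    list(image = img, annotations = annotations)
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_images` PNG scenes plus one COCO JSON per split and a manifest
#' recording the seed and the full specification.
#'
#' @param spec a [scene_spec()].
#' @param n_images number of scenes.
#' @param out_dir output directory.
#' @param split split name (file prefix and JSON name).
#' @param seed base seed; scene `i` uses `seed + i - 1`.
#' @return the manifest list (invisibly written as `manifest_<split>.json`).
#' @export
generate_dataset <- function(spec = default_spec(), n_images = 10L,
                             out_dir = ".", split = "train", seed = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  images <- vector("list", n_images)
  anns <- list()
  aid <- 0L
  for (i in seq_len(n_images)) {
    sc <- generate_scene(spec, seed + i - 1L)
    fname <- sprintf("%s_%04d.png", split, i)
    png::writePNG(sc$image, file.path(out_dir, fname))
    images[[i]] <- data.frame(id = i, file_name = fname,
                              width = spec$img_size, height = spec$img_size,
                              stringsAsFactors = FALSE)
    if (nrow(sc$annotations) > 0) {
      a <- sc$annotations
      a$image_id <- i
      a$iscrowd <- 0L
      a$area <- a$w * a$h
      a$score <- NA_real_
      a$id <- aid + seq_len(nrow(a))
      aid <- aid + nrow(a)
      anns[[length(anns) + 1L]] <-
        a[, c("id", "image_id", "category_id", "x", "y", "w", "h",
              "area", "iscrowd", "score")]
    }
  }
  ds <- list(
    images = do.call(rbind, images),
    annotations = if (length(anns)) do.call(rbind, anns) else
      data.frame(id = integer(), image_id = integer(), category_id = integer(),
                 x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                 area = numeric(), iscrowd = integer(), score = numeric()),
    categories = data.frame(id = 1:5, name = palm_classes(),
                            stringsAsFactors = FALSE))
  json_path <- file.path(out_dir, paste0(split, ".json"))
  write_coco(ds, json_path)
  manifest <- list(split = split, n_images = n_images, seed = seed,
                   annotations = json_path,
                   n_annotations = nrow(ds$annotations),
                   spec = unclass(spec))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", split, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# convert a COCO dataset into the in-memory training-batch format used by
# fit_detector(): letterboxed image array + normalized corner boxes
coco_to_batch <- function(ds, dir, img_size) {
  n <- nrow(ds$images)
  x <- array(0, c(3L, img_size, img_size, n))
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    im <- ds$images[i, ]
    png <- png::readPNG(file.path(dir, im$file_name))
    lb <- letterbox(png, target = img_size)
    xi <- aperm(lb$image, c(3, 1, 2))
    dim(xi) <- c(3L, img_size, img_size, 1L)
    x[, , , i] <- xi
    an <- ds$annotations[ds$annotations$image_id == im$id, , drop = FALSE]
    if (nrow(an) > 0) {
      b <- xywh_to_xyxy(as.matrix(an[, c("x", "y", "w", "h")]))
      b <- letterbox_boxes(b, lb) / img_size
      targets[[i]] <- list(boxes = b, classes = an$category_id)
    } else {
      targets[[i]] <- list(boxes = matrix(0, 0, 4), classes = integer(0))
    }
  }
  list(x = x, targets = targets)
}
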