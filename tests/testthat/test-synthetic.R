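# Synthetic plantation scenes: determinism, annotation consistency, and the
# class-imbalance / small-object statistics they are meant to emulate.

test_that("default spec reproduces the survey's class imbalance", {
  sp <- default_spec()
  expect_equal(sum(sp$class_probs), 1, tolerance = 1e-12)
  tot <- 201303 + 599 + 953 + 3103 + 56893
  expect_equal(unname(sp$class_probs["healthy"]), 201303 / tot, tolerance = 1e-9)
  expect_equal(unname(sp$class_probs["dead"]), 599 / tot, tolerance = 1e-9)
  expect_equal(unname(sp$class_probs["small"]), 56893 / tot, tolerance = 1e-9)
  spv <- default_spec("val")
  vtot <- 24884 + 61 + 95 + 411 + 7395
  expect_equal(unname(spv$class_probs["dead"]), 61 / vtot, tolerance = 1e-9)
  expect_error(scene_spec(class_probs = c(healthy = 0.5, dead = 0.1, grass = 0.1,
                                          yellow = 0.1, small = 0.1)), "sum to 1")
  expect_error(scene_spec(grid_spacing = 4), "too dense")
})

test_that("scene generation is a pure function of (spec, seed)", {
  sp <- default_spec()
  a <- generate_scene(sp, seed = 9)
  b <- generate_scene(sp, seed = 9)
  expect_identical(a, b)
  c <- generate_scene(sp, seed = 10)
  expect_false(identical(a$image, c$image))
})

test_that("annotations lie inside the image with positive area", {
  sp <- default_spec()
  for (s in 1:5) {
    an <- generate_scene(sp, s)$annotations
    expect_true(all(an$x >= 0 & an$y >= 0))
    expect_true(all(an$x + an$w <= sp$img_size & an$y + an$h <= sp$img_size))
    expect_true(all(an$w > 0 & an$h > 0))
    expect_true(all(an$category_id %in% 1:5))
  }
})

test_that("annotations are consistent with rendered content", {
  # the box edge must touch actual plant pixels: the crop inside the box
  # differs from background more than the ring just outside it
  sp <- scene_spec(grid_spacing = 64, occupancy = 1, noise_sd = 0)
  sc <- generate_scene(sp, 3)
  an <- sc$annotations
  g <- sc$image[, , 2]  # green channel separates canopy from soil
  for (i in seq_len(min(5, nrow(an)))) {
    ys <- (an$y[i] + 1):(an$y[i] + an$h[i])
    xs <- (an$x[i] + 1):(an$x[i] + an$w[i])
    inside <- g[ys, xs]
    expect_gt(stats::sd(as.vector(inside)), 0.01)  # textured object present
  }
})

test_that("sampled class frequencies follow the specified multinomial", {
  sp <- default_spec()
  counts <- integer(5)
  for (s in 1:80) {
    an <- generate_scene(sp, 2000 + s)$annotations
    counts <- counts + tabulate(an$category_id, 5)
  }
  p <- stats::chisq.test(counts, p = unname(sp$class_probs))$p.value
  expect_gt(p, 0.01)
})

test_that("a substantial fraction of boxes is in the small-object regime", {
  sp <- default_spec()
  small <- 0L; total <- 0L
  for (s in 1:20) {
    an <- generate_scene(sp, 3000 + s)$annotations
    small <- small + sum(an$w < 32 & an$h < 32)
    total <- total + nrow(an)
  }
  expect_gte(small / total, 0.30)
})

test_that("dataset writing round-trips and conserves annotation counts", {
  td <- withr::local_tempdir()
  sp <- default_spec()
  man <- generate_dataset(sp, 4, td, "train", seed = 11)
  expect_length(list.files(td, pattern = "\\.png$"), 4)
  ds <- read_coco(file.path(td, "train.json"))
  expect_equal(nrow(ds$images), 4)
  expect_equal(nrow(ds$annotations), man$n_annotations)
  # conservation: JSON count equals the sum of per-scene counts
  per_scene <- sapply(1:4, function(i)
    nrow(generate_scene(sp, 11 + i - 1)$annotations))
  expect_equal(nrow(ds$annotations), sum(per_scene))
  # pngs round-trip the rendered 8-bit image exactly
  img <- png::readPNG(file.path(td, ds$images$file_name[1]))
  expect_equal(img, generate_scene(sp, 11)$image, tolerance = 1e-7)
  # manifest records seed and spec
  mf <- jsonlite::read_json(file.path(td, "manifest_train.json"))
  expect_equal(mf$seed, 11)
  expect_equal(mf$spec$img_size, sp$img_size)
})
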