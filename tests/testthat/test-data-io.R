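test_that("the synthetic generator is deterministic with independent substreams", {
  spec <- synthetic_spec(n_classes = 3, n_per_class = 3, size = c(24, 24), seed = 5)
  d1 <- generate_synthetic_dataset(spec)
  d2 <- generate_synthetic_dataset(spec)
  expect_identical(d1$image, d2$image)
  expect_equal(nrow(d1), 9)
  expect_true(all(vapply(d1$image, function(m) all(m >= 0 & m <= 255), logical(1))))
  # adding a class must not perturb earlier classes' pixels
  d3 <- generate_synthetic_dataset(
    synthetic_spec(n_classes = 4, n_per_class = 3, size = c(24, 24), seed = 5))
  expect_identical(d3$image[d3$class <= 3], d1$image)
})

test_that("zero noise and zero jitter reproduce the class template exactly", {
  spec <- synthetic_spec(n_classes = 2, n_per_class = 3, size = c(24, 24),
                         noise_sigma = 0, max_shift = 0, max_rotation = 0,
                         intensity_jitter = 0, seed = 8)
  d <- generate_synthetic_dataset(spec)
  for (cls in 1:2) {
    imgs <- d$image[d$class == cls]
    expect_identical(imgs[[1]], imgs[[2]])
    expect_identical(imgs[[1]], imgs[[3]])
  }
  # different classes draw different vein layouts
  expect_false(identical(d$image[d$class == 1][[1]], d$image[d$class == 2][[1]]))
})

test_that("within-class image correlation exceeds between-class correlation", {
  d <- generate_synthetic_dataset(synthetic_spec(seed = 3))
  vecs <- vapply(d$image, as.vector, numeric(48 * 48))
  cm <- stats::cor(vecs)
  same <- outer(d$class, d$class, "==") & upper.tri(cm)
  diff <- outer(d$class, d$class, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff]))
})

test_that("dataset splitting follows the first-n-train protocol", {
  d <- generate_synthetic_dataset(
    synthetic_spec(n_classes = 2, n_per_class = 4, size = c(16, 16), seed = 2))
  sp <- split_dataset(d, 3)
  expect_equal(sum(sp$split == "test"), 2)
  expect_true(all(sp$split[sp$sample <= 3] == "train"))
})

test_that("PNG loading, rotation and resizing behave as documented", {
  dir <- withr::local_tempdir()
  set.seed(71)
  img <- matrix(round(runif(48 * 48, 0, 255)), 48, 48)
  p <- file.path(dir, "x.png")
  png::writePNG(img / 255, p)
  # identity path: already grayscale at target size
  back <- load_and_preprocess(p, target_size = c(48, 48))
  expect_equal(back, img, tolerance = 1)
  # two counterclockwise quarter turns equal a half turn
  r2 <- spikevein:::rotate_ccw90(spikevein:::rotate_ccw90(img))
  expect_equal(r2, img[nrow(img):1, ncol(img):1])
  # bilinear resize preserves constants
  cimg <- matrix(100, 30, 40)
  pc <- file.path(dir, "c.png")
  png::writePNG(cimg / 255, pc)
  rc <- load_and_preprocess(pc, target_size = c(48, 48))
  expect_equal(max(abs(rc - 100)), 0, tolerance = 0.5)
  expect_error(load_and_preprocess(file.path(dir, "missing.png")), "cannot read")
  expect_error(load_and_preprocess(p, target_size = c(0, 10)), "zero-size")
})

test_that("dataset PNG export writes a manifest and readable images", {
  d <- generate_synthetic_dataset(
    synthetic_spec(n_classes = 2, n_per_class = 2, size = c(16, 16), seed = 4))
  d <- split_dataset(d, 1)
  dir <- withr::local_tempdir()
  man <- write_dataset_png(d, dir)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$path)))
  img <- load_and_preprocess(man$path[1], target_size = NULL)
  expect_equal(dim(img), c(16, 16))
  expect_lt(max(abs(img - d$image[[1]])), 1)
})

make_synthetic_finger <- function(H = 160, W = 120, top = 60, bottom = 120) {
  img <- matrix(20, H, W)
  img[top:bottom, ] <- 180
  img
}

test_that("ROI extraction recovers the bright finger band", {
  img <- make_synthetic_finger()
  roi <- extract_roi_canny(img, top_crop = 20, bottom_crop = 10,
                           target_size = c(48, 48))
  expect_equal(dim(roi), c(48, 48))
  # interior of the recovered ROI is finger tissue, not background
  expect_gt(mean(roi[10:38, ]), 150)
  # the detected band edges sit within +-2 px of the constructed boundaries
  cropped_top <- 60 - 20   # band start after cropping
  cropped_bot <- 120 - 20
  edges <- canny_edges(img[21:150, ])
  tops <- apply(edges, 2, function(cc) if (any(cc)) which(cc)[1] else NA)
  bots <- apply(edges, 2, function(cc) if (any(cc)) max(which(cc)) else NA)
  expect_lt(abs(stats::median(tops, na.rm = TRUE) - cropped_top), 2.5)
  expect_lt(abs(stats::median(bots, na.rm = TRUE) - cropped_bot), 2.5)
  expect_error(extract_roi_canny(matrix(50, 100, 80), top_crop = 10, bottom_crop = 10),
               "no detectable contours")
  expect_error(extract_roi_canny(matrix(50, 30, 80)), "taller")
})

test_that("YAML configuration maps onto the constructor arguments", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "input_size: 32",
    "seed: 11",
    "filters:",
    "  gabor: {window: 9}",
    "  dog: {window: 5}",
    "  cutoff: 40",
    "encode: {t_max: 10, norm_radius: 4}",
    "stdp: {a_plus: 0.01, a_minus: -0.0075}",
    "layer1: {out_channels: 8, kernel: 3, epochs: 1, kwta: 3, inhibition_radius: 1}",
    "layer2: {out_channels: 10, kernel: 2, epochs: 2, kwta: 2, inhibition_radius: 1}"
  ), yml)
  cfg <- config_from_yaml(yml)
  expect_equal(cfg$input_size, 32)
  expect_equal(cfg$t_max, 10)
  expect_equal(cfg$bank$cutoff, 40)
  expect_length(cfg$bank$kernels, 6)
  expect_equal(nrow(cfg$bank$kernels[[1]]), 9)
  expect_equal(cfg$layers[[1]]$out_channels, 8)
  expect_equal(cfg$layers[[1]]$a_plus, 0.01)
  expect_equal(cfg$layers[[2]]$out_channels, 10)
  expect_equal(cfg$seed, 11)
})
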