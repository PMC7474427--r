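test_that("double 180-degree rotation is the identity", {
  img <- random_image(1)
  expect_equal(gt_rotate(gt_rotate(img))$pixels, img$pixels)
  expect_equal(gt_rotate(gt_rotate(img, "vflip"), "vflip")$pixels, img$pixels)
  flat <- spectrogram_image(array(0.3, c(64, 64, 3)), "left")
  expect_equal(gt_rotate(flat)$pixels, flat$pixels)
})

test_that("rotation maps (r, c) to (63-r, 63-c) like a brute-force loop", {
  img <- random_image(2)
  rot <- gt_rotate(img)
  ref <- array(0, c(64, 64, 3))
  for (r in 1:64) for (c in 1:64) ref[r, c, ] <- img$pixels[65 - r, 65 - c, ]
  expect_identical(rot$pixels, ref)
})

test_that("shifting fills vacated columns with noise and moves content", {
  img <- random_image(3)
  set.seed(11)
  sh <- gt_shift(img, dx = 5, dy = 0)
  expect_equal(sh$pixels[, 6:64, ], img$pixels[, 1:59, ])
  expect_false(any(sh$pixels[, 1:5, ] == img$pixels[, 1:5, ]))
  set.seed(11)
  expect_equal(gt_shift(img, 0, 0)$pixels[, , ], {
    set.seed(11); gt_shift(img, 0, 0)$pixels
  })
  id <- gt_shift(img, 0, 0)
  expect_equal(id$pixels, img$pixels)
  expect_error(gt_shift(img, 20, 0, shift_max = 8), "shift_max")
})

test_that("color jitter honors explicit offsets and clips to [0, 1]", {
  half <- spectrogram_image(array(0.5, c(64, 64, 3)), "right")
  up <- gt_color(half, brightness_offset = 0.1, contrast_factor = 1)
  expect_equal(unique(as.vector(up$pixels)), 0.6)
  idn <- gt_color(half, brightness = 0, contrast = 0)
  expect_equal(idn$pixels, half$pixels)
  img <- random_image(4)
  out <- gt_color(img, brightness_offset = 0.9, contrast_factor = 1.5)
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("noise addition obeys the uniform bound and zero-scale identity", {
  img <- random_image(5)
  expect_equal(noise_addition(img, 0)$pixels, img$pixels)
  mid <- spectrogram_image(array(0.5, c(64, 64, 3)), "left")
  set.seed(21)
  out <- noise_addition(mid, 0.4)
  # no clipping can occur for a 0.5 image at scale 0.4, so the raw bound shows
  expect_true(all(abs(out$pixels - 0.5) <= 0.5 * 0.4 + 1e-12))
  expect_error(noise_addition(img, -1), "noise_scale")
})

test_that("uniform perturbations are centred at zero", {
  set.seed(31)
  n <- 1e5
  u <- stats::runif(n, -0.5, 0.5)
  se <- stats::sd(u) / sqrt(n)
  expect_lt(abs(mean(u)), 3 * se)
  # and through the augmenter on a mid-gray image (no clipping)
  mid <- spectrogram_image(array(0.5, c(64, 64, 3)), "left")
  set.seed(32)
  diffs <- noise_addition(mid, 0.3)$pixels - 0.5
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("augmenters preserve labels and subject metadata", {
  img <- spectrogram_image(array(0.4, c(64, 64, 3)), "right",
                           subject_id = "s07")
  for (out in list(gt_rotate(img), gt_shift(img, 2, -3), gt_color(img),
                   noise_addition(img, 0.2))) {
    expect_identical(out$label, "right")
    expect_identical(out$subject_id, "s07")
    expect_true(out$provenance %in% c("gt", "na"))
    expect_true(all(out$pixels >= 0 & out$pixels <= 1))
    expect_identical(dim(out$pixels), c(64L, 64L, 3L))
  }
})

test_that("batch augmentation is deterministic given the seed", {
  imgs <- lapply(1:4, random_image)
  a <- augment_images(imgs, "gt", 12, augment_config(), seed = 5)
  b <- augment_images(imgs, "gt", 12, augment_config(), seed = 5)
  expect_identical(a, b)
  expect_length(a, 12)
  n <- augment_images(imgs, "na", 7, augment_config(noise_scale = 0.3,
                                                    method = "na"), seed = 2)
  expect_identical(unique(image_provenance(n)), "na")
})
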