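test_that("gamma transform reproduces the power law and its identities", {
  # normalized r = 0.25 (gray 63.75 ~ 64), gamma 0.5, c 1 -> s = 0.5
  img <- gray_image(matrix(c(0, 64, 255, 128), 2, 2))
  out <- unclass(gamma_transform(img, gamma = 0.5, c = 1))
  expect_equal(out[1, 1], 0)                       # r = 0 -> 0
  expect_equal(out[2, 1], round(sqrt(64 / 255) * 255))
  expect_equal(out[1, 2], 255)                     # r = 1 -> 1
  any_img <- gray_image(matrix(sample(0:255, 100, TRUE), 10, 10))
  expect_equal(unclass(gamma_transform(any_img, gamma = 1, c = 1)),
               unclass(any_img), ignore_attr = TRUE)
  # gamma < 1 with c = 1 brightens pixelwise
  expect_true(all(unclass(gamma_transform(any_img, 0.5, 1)) >= unclass(any_img)))
  expect_error(gamma_transform(any_img, gamma = 0), "positive")
  expect_error(gamma_transform(any_img, gamma = -2), "positive")
})

test_that("fuzzy intensification fixes mid-gray, preserves constants, widens mid-range gaps", {
  expect_equal(unclass(fuzzy_enhance(matrix(128, 4, 4)))[1, 1], 128)
  const <- matrix(77, 5, 5)
  out_const <- unclass(fuzzy_enhance(const))
  expect_length(unique(as.vector(out_const)), 1L)   # constant in, constant out
  two <- unclass(fuzzy_enhance(matrix(c(100, 160), 2, 1)))
  expect_gt(abs(diff(as.vector(two))), 60)          # gap strictly widened
  rng <- unclass(fuzzy_enhance(matrix(0:255, 16, 16)))
  expect_true(all(rng >= 0 & rng <= 255))
})

test_that("histogram equalization: constants fixed, uniform histogram ~ identity, ramp flattens", {
  const <- matrix(200, 6, 6)
  expect_equal(unclass(equalize_hist(const)), const, ignore_attr = TRUE)

  uniform <- matrix(rep(0:255, each = 4), 32, 32)   # every level equally often
  eq <- unclass(equalize_hist(uniform))
  expect_lte(max(abs(eq - uniform)), 1)

  # a compressed ramp spreads over the full range: the 16-bin histogram gets
  # closer to uniform (256-bin counts are merely repositioned, so coarse bins
  # are the right resolution for this property)
  ramp <- matrix(rep(seq(80, 160, length.out = 256), each = 4), 32, 32)
  ramp <- round(ramp)
  chisq_uniform16 <- function(v) {
    h <- tabulate(as.integer(v) %/% 16L + 1L, 16L)
    e <- length(v) / 16
    sum((h - e)^2 / e)
  }
  expect_lt(chisq_uniform16(unclass(equalize_hist(ramp))), chisq_uniform16(ramp))
})

test_that("equalize_hist agrees with EBImage's equalization", {
  withr::with_seed(7, v <- matrix(sample(40:180, 48 * 48, TRUE), 48))
  mine <- unclass(equalize_hist(v))
  ref <- round(t(EBImage::imageData(
    EBImage::equalize(EBImage::Image(t(v / 255)), range = c(0, 1), levels = 256))) * 255)
  expect_equal(mine, ref, ignore_attr = TRUE)
})

test_that("the preprocessing chain composes, is toggleable and deterministic", {
  cfg <- ldh_config()$preprocess
  off <- modifyList(cfg, list(open = FALSE, gamma_enabled = FALSE,
                              fuzzy = FALSE, equalize = FALSE))
  img <- gray_image(matrix(sample(0:255, 400, TRUE), 20, 20), 0.5)
  expect_equal(unclass(preprocess(img, off)), unclass(img), ignore_attr = TRUE)
  a <- preprocess(img, cfg)
  b <- preprocess(img, cfg)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(unclass(a) >= 0 & unclass(a) <= 255))
})

test_that("default preprocessing keeps phantom vertebrae brighter than background", {
  ph <- demo_phantom()
  pre <- unclass(preprocess(ph$clean, ldh_config()$preprocess))
  vmask <- Reduce(`|`, ph$truth$vertebra_masks)
  bg <- !Reduce(`|`, c(ph$truth$vertebra_masks, ph$truth$disc_masks,
                       list(ph$truth$canal_mask)))
  expect_gt(mean(pre[vmask]), mean(pre[bg]))
})
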