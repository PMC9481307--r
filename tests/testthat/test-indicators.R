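vline <- function(x0) demarcation_line(c(x0, 0), c(x0, 100))

test_that("split_disc partitions exactly, with on-line pixels counted normal", {
  pix <- ellipse_pixels(50, 50, 20, 8)
  ln <- vline(70)                                   # disc entirely anterior
  parts <- split_disc(pix, ln)
  expect_equal(nrow(parts$protrusion), 0L)
  expect_equal(nrow(parts$normal), nrow(pix))

  ln2 <- vline(50)                                  # bisect through the centroid
  parts2 <- split_disc(pix, ln2)
  expect_equal(nrow(parts2$protrusion) + nrow(parts2$normal), nrow(pix))
  expect_lt(abs(nrow(parts2$protrusion) / nrow(pix) - 0.5), 0.02)
  # pixels exactly on the line are normal
  on_line <- parts2$normal[parts2$normal[, 1] == 50, , drop = FALSE]
  expect_gt(nrow(on_line), 0L)
})

test_that("phantom bump pixels equal the split's protrusion part", {
  ph <- demo_phantom()
  H <- nrow(ph$clean)
  i <- 3                                            # the protrusion-grade disc
  idx <- which(ph$truth$disc_masks[[i]])
  pix <- cbind(x = (idx - 1) %/% H, y = (idx - 1) %% H)
  parts <- split_disc(pix, ph$truth$lines[[i]])
  a_px <- ph$truth$spec$protrusion_area_mm2[i] / ph$truth$spec$pixel_spacing_mm^2
  expect_lt(abs(nrow(parts$protrusion) - a_px) / a_px, 0.03)
})

test_that("protrusion distance is the max point-line distance, scaled by spacing", {
  ln <- vline(10)
  expect_equal(protrusion_distance(matrix(numeric(0), 0, 2), ln, 0.5), 0)
  expect_equal(protrusion_distance(cbind(20, 5), ln, 0.5), 5)   # 10 px * 0.5
  expect_error(protrusion_distance(cbind(20, 5), ln, NA), "is.finite")
})

test_that("protrusion distance matches a brute-force oracle on random discs", {
  worst <- 0
  withr::with_seed(202, {
    for (k in 1:50) {
      pix <- ellipse_pixels(runif(1, 40, 80), runif(1, 40, 80),
                            runif(1, 8, 25), runif(1, 4, 12))
      p1 <- c(runif(1, 30, 90), runif(1, 0, 20))
      p2 <- c(runif(1, 30, 90), runif(1, 80, 100))
      ln <- demarcation_line(p1, p2)
      parts <- split_disc(pix, ln)
      if (nrow(parts$protrusion) == 0) next
      got <- protrusion_distance(parts$protrusion, ln, 0.7)
      # oracle: explicit two-point point-line distance, maximized by loop
      best <- 0
      for (r in seq_len(nrow(parts$protrusion))) {
        p <- parts$protrusion[r, ]
        num <- abs((p2[1] - p1[1]) * (p1[2] - p[2]) - (p1[1] - p[1]) * (p2[2] - p1[2]))
        best <- max(best, num / sqrt(sum((p2 - p1)^2)))
      }
      worst <- max(worst, abs(got - best * 0.7) / max(best * 0.7, 1e-12))
    }
  })
  expect_lt(worst, 1e-9)
})

test_that("indicator vectors: trivial disc, unit scaling, symmetry invariances", {
  img <- matrix(40, 120, 120)
  pix <- ellipse_pixels(60, 60, 20, 8)
  v <- compute_indicators(pix, vline(90), img, 0.5)
  expect_equal(unname(v), c(0, 0, 0, 0, 40))

  ln <- vline(60)
  v1 <- compute_indicators(pix, ln, img, 0.5)
  expect_lt(abs(v1[["area_ratio"]] - 0.5), 0.02)    # symmetric split
  v2 <- compute_indicators(pix, ln, img, 1.0)
  expect_equal(v2[["distance_mm"]], 2 * v1[["distance_mm"]])  # spacing doubles
  expect_equal(v2[["area_mm2"]], 4 * v1[["area_mm2"]])        # area quadruples
  expect_equal(v2[["area_ratio"]], v1[["area_ratio"]])
  expect_equal(v2[["length_ratio"]], v1[["length_ratio"]])

  # translation invariance (geometry only; gray read from a flat image)
  shift <- cbind(pix[, 1] + 7, pix[, 2] + 11)
  v3 <- compute_indicators(shift, vline(67), matrix(40, 150, 150), 0.5)
  expect_equal(v3[1:4], v1[1:4])
  # y-reflection invariance
  refl <- cbind(pix[, 1], 120 - pix[, 2])
  v4 <- compute_indicators(refl, ln, matrix(40, 150, 150), 0.5)
  expect_equal(v4[1:4], v1[1:4], tolerance = 1e-12)
  expect_error(compute_indicators(matrix(numeric(0), 0, 2), ln, img, 0.5),
               "no pixels")
})

test_that("degeneration flags use a strict threshold", {
  grays <- c(27.06, 50.83, 55.44, 49.95, 47.41, 24.02, 19.42, 24.56)
  fl <- degeneration_flags(grays, threshold = 20)
  expect_identical(which(fl), 7L)
  expect_equal(grays[fl], 19.42)
  expect_false(any(degeneration_flags(c(20, 25, 200))))
  expect_false(degeneration_flags(20.0))            # exactly 20: not flagged
  expect_true(degeneration_flags(19.999))
  expect_error(degeneration_flags(c(-5, 20)), "mean_grays")
})
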