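test_that("contour features are re-derivable from the boundary and pixels", {
  mask <- rect_mask(40, 40, 6, 25, 6, 30)          # 20 rows x 25 cols
  ct <- extract_contours(mask)[[1]]
  expect_equal(ct$npix, 20 * 25)
  expect_equal(unname(ct$bbox), c(5, 5, 25, 20))   # 0-based x, y, w, h
  expect_equal(ct$aspect_ratio, 25 / 20)
  expect_equal(ct$area_px, 24 * 19)                # shoelace of the boundary
  expect_equal(ct$perimeter_px, 2 * (24 + 19))
  # shoelace and chain length recomputed independently from the points
  p <- ct$points
  nn <- c(seq_len(nrow(p))[-1], 1L)
  expect_equal(abs(sum(p[, 1] * p[nn, 2] - p[nn, 1] * p[, 2])) / 2, ct$area_px)
  expect_equal(sum(sqrt(rowSums((p[nn, ] - p)^2))), ct$perimeter_px)
})

test_that("vertebra screening applies the three printed rules", {
  cfg <- ldh_config()$vertebra
  sq <- extract_contours(rect_mask(100, 100, 11, 80, 11, 80))[[1]]  # 70x70
  expect_length(screen_contours(list(sq), cfg), 1L)
  bar <- extract_contours(rect_mask(250, 40, 21, 230, 11, 20))[[1]] # 210x10
  expect_length(screen_contours(list(bar), cfg), 0L)                # aspect
  tiny <- extract_contours(rect_mask(20, 20, 5, 14, 5, 14))[[1]]    # 10x10
  expect_length(screen_contours(list(tiny), cfg), 0L)               # area
  # every survivor satisfies all three rules re-derived from points
  keep <- screen_contours(list(sq, bar, tiny), cfg)
  for (ct in keep) {
    expect_true(ct$area_px >= cfg$area_min_px && ct$area_px <= cfg$area_max_px)
    expect_true(ct$aspect_ratio >= cfg$aspect_min && ct$aspect_ratio <= cfg$aspect_max)
    expect_lt(ct$perimeter_px, cfg$perimeter_max_px)
  }
  # survivors sorted top to bottom
  two <- matrix(FALSE, 200, 100)
  two[120:179, 16:85] <- TRUE; two[10:69, 16:85] <- TRUE
  srt <- screen_contours(extract_contours(two), cfg)
  ys <- vapply(srt, function(ct) ct$centroid[["y"]], numeric(1))
  expect_false(is.unsorted(ys))
})

test_that("total-least-squares line fit recovers orientation", {
  rect <- extract_contours(rect_mask(60, 80, 16, 45, 6, 75))[[1]]   # wide
  expect_equal(unname(fit_line(rect)["slope"]), 0, tolerance = 1e-8)

  # rectangle rotated by 30 degrees: slope tan(30) within 0.02
  th <- 30 * pi / 180
  X <- matrix(rep(0:199, each = 200), 200, 200)
  Y <- matrix(rep(0:199, times = 200), 200, 200)
  u <- (X - 100) * cos(th) + (Y - 100) * sin(th)
  v <- -(X - 100) * sin(th) + (Y - 100) * cos(th)
  rot <- abs(u) <= 45 & abs(v) <= 20
  ctr <- extract_contours(rot)[[1]]
  expect_equal(abs(unname(fit_line(ctr)["slope"])), tan(th), tolerance = 0.02)

  tall <- extract_contours(rect_mask(80, 60, 6, 75, 26, 35))[[1]]
  expect_equal(unname(fit_line(tall)["slope"]), Inf)
  degen <- list(points = matrix(c(3, 3, 3, 3), 2, 2))
  expect_error(fit_line(degen), "identical")
})

test_that("corner localization: box corners upright, poles for the caudal case", {
  rect <- extract_contours(rect_mask(50, 60, 11, 30, 6, 45))[[1]]
  cr <- locate_corners(rect, is_caudal = FALSE)
  expect_equal(cr$anterior_superior, c(x = 5, y = 10))
  expect_equal(cr$posterior_superior, c(x = 44, y = 10))
  expect_equal(cr$anterior_inferior, c(x = 5, y = 29))
  expect_equal(cr$posterior_inferior, c(x = 44, y = 29))

  # diamond: poles are the four vertices
  X <- matrix(rep(0:60, each = 61), 61, 61)
  Y <- matrix(rep(0:60, times = 61), 61, 61)
  diamond <- abs(X - 30) / 20 + abs(Y - 30) / 12 <= 1
  dct <- extract_contours(diamond)[[1]]
  pc <- locate_corners(dct, is_caudal = TRUE)
  expect_setequal(vapply(pc, function(p) paste(p, collapse = ","), character(1)),
                  c("30,18", "30,42", "10,30", "50,30"))

  # translation equivariance
  m1 <- rect_mask(60, 60, 11, 30, 6, 45)
  m2 <- rect_mask(60, 60, 21, 40, 16, 55)
  c1 <- locate_corners(extract_contours(m1)[[1]])
  c2 <- locate_corners(extract_contours(m2)[[1]])
  for (nm in names(c1)) expect_equal(c2[[nm]] - c1[[nm]], c(x = 10, y = 10))
})

test_that("corner localization on the phantom's caudal vertebra is pixel-accurate", {
  ph <- demo_phantom()
  n <- length(ph$truth$vertebra_masks)
  ct <- extract_contours(ph$truth$vertebra_masks[[n]])[[1]]
  sl <- fit_line(ct)["slope"]
  expect_true(abs(sl) >= 0.1 && abs(sl) <= 1)     # caudal slope band
  cr <- locate_corners(ct, is_caudal = TRUE)
  # detected posterior-superior pole within 2 px of the rendered vertex
  mask <- ph$truth$vertebra_masks[[n]]
  idx <- which(mask)
  px <- (idx - 1) %/% nrow(mask); py <- (idx - 1) %% nrow(mask)
  rendered_ps <- c(max(px), py[which.max(px)])
  expect_lte(max(abs(unname(cr$posterior_superior) - rendered_ps)), 2)
})

test_that("demarcation lines join posterior corners, one per adjacent pair", {
  # two stacked rectangles with equal x-extent -> vertical line at shared x
  up <- list(corners = list(posterior_inferior = c(40, 20)))
  lo <- list(corners = list(posterior_superior = c(40, 50)))
  ln <- demarcation_line(up$corners$posterior_inferior, lo$corners$posterior_superior)
  expect_equal(c(ln$a, ln$b), c(1, 0))
  expect_equal(ln$d, -40)
  expect_equal(unname(signed_distance(ln, cbind(45, 35))), 5)
  expect_equal(unname(signed_distance(ln, cbind(40, 35))), 0)
  expect_error(demarcation_line(c(1, 2), c(1, 2)), "coincide")
  expect_length(demarcation_lines(list()), 0L)

  ph <- demo_phantom()
  verts <- detect_vertebrae(ph$clean, phantom_pipeline_config()$vertebra)
  lines <- demarcation_lines(verts)
  expect_length(lines, length(verts) - 1L)        # 6 vertebrae -> 5 lines
  # detected lines match the rendered truth lines to within 2 px RMS
  for (i in seq_along(lines)) {
    tru <- ph$truth$lines[[i]]
    rms <- sqrt(mean(c(sum((lines[[i]]$p_top - tru$p_top)^2),
                       sum((lines[[i]]$p_bottom - tru$p_bottom)^2)) / 2))
    expect_lt(rms, 2)
  }
})
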