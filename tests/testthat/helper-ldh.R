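# shared fixtures: one class-spanning phantom (normal/bulge/protrusion/
# extrusion + caudal-adjacent normal), rendered once per test run
demo_spec <- function(noise_sigma = 0, seed = 1L, canal_interrupted = FALSE) {
  phantom_spec(disc_intensity = c(215, 215, 210, 70, 215),
               protrusion_distance_mm = c(0, 3, 7, 12, 0),
               protrusion_area_mm2 = c(0, 40, 150, 250, 0),
               canal_interrupted = canal_interrupted,
               noise_sigma = noise_sigma, rng_seed = seed)
}

demo_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(demo_spec())
    cache
  }
})

# 0-based pixel matrix -> linear ids for IoU computations
pixel_ids <- function(pix, H) pix[, 2] + 1 + pix[, 1] * H

# does any contour cover the mask with IoU >= 0.5?
mask_recovered <- function(mask, contours) {
  midx <- which(mask)
  H <- nrow(mask)
  for (ct in contours) {
    cidx <- pixel_ids(ct$pixels, H)
    if (length(intersect(midx, cidx)) / length(union(midx, cidx)) >= 0.5)
      return(TRUE)
  }
  FALSE
}

# synthetic blob pixel sets for geometry tests: filled ellipse, 0-based
ellipse_pixels <- function(cx, cy, a, b) {
  xs <- seq(floor(cx - a), ceiling(cx + a))
  ys <- seq(floor(cy - b), ceiling(cy + b))
  g <- expand.grid(x = xs, y = ys)
  g <- g[((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1, ]
  as.matrix(g)
}

# mask with a filled rectangle (1-based row/col bounds)
rect_mask <- function(nrow, ncol, r0, r1, c0, c1) {
  m <- matrix(FALSE, nrow, ncol)
  m[r0:r1, c0:c1] <- TRUE
  m
}
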