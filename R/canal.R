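#' Identify the spinal canal and decide its continuity
#'
#' Candidate contours are taken from the disc-stage binary mask (the canal is
#' bright on T2, like the discs): a contour is a canal candidate when its
#' leftmost x lies within a window to the right of the mean posterior edge of
#' the vertebrae (`mean` over vertebrae of each contour's maximum x, offset
#' by `[x_offset_min_px, x_offset_max_px]`). The canal is continuous when the
#' candidates' pixels, projected on y, cover at least `min_vertical_coverage`
#' of the vertebral column's vertical extent in a single unbroken run --
#' extruded disc material interrupts the band and breaks the run.
#'
#' @param mask Disc-stage logical mask (see [segment_discs()]).
#' @param vertebrae Non-empty list of `ldh_vertebra` (defines the window).
#' @param cfg The `canal` block of [ldh_config()].
#' @return List with `candidates` (contours), `continuous` (flag) and
#'   `coverage` (largest single covered fraction of the column extent).
#' @export
find_canal <- function(mask, vertebrae, cfg = ldh_config()$canal) {
  if (length(vertebrae) == 0L)
    stop("find_canal needs at least one vertebra to define the search window")
  post_x <- mean(vapply(vertebrae, function(v) max(v$contour$pixels[, 1]), numeric(1)))
  win <- post_x + c(cfg$x_offset_min_px, cfg$x_offset_max_px)
  cts <- extract_contours(mask)
  cands <- Filter(function(ct) {
    lx <- min(ct$pixels[, 1])
    lx >= win[1] && lx <= win[2]
  }, cts)
  ys <- unlist(lapply(vertebrae, function(v) range(v$contour$pixels[, 2])))
  y0 <- min(ys); y1 <- max(ys)
  extent <- y1 - y0 + 1
  covered <- rep(FALSE, extent)
  for (ct in cands) {
    yy <- ct$pixels[, 2]
    yy <- yy[yy >= y0 & yy <= y1]
    covered[unique(yy) - y0 + 1L] <- TRUE
  }
  runs <- rle(covered)
  best <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  coverage <- best / extent
  list(candidates = cands,
       continuous = coverage >= cfg$min_vertical_coverage,
       coverage = coverage)
}
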