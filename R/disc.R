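#' Segment intervertebral discs by global thresholding
#'
#' Discs (and the spinal canal) are bright on T2: foreground pixels are those
#' with intensity at or above `gray_threshold`, i.e. everything below the
#' threshold goes to background. A small morphological opening (default 2x2
#' elliptical element) then removes speckle.
#'
#' @param img Preprocessed [gray_image()] or 0-255 matrix.
#' @param cfg The `disc` block of [ldh_config()].
#' @return Logical mask.
#' @export
segment_discs <- function(img, cfg = ldh_config()$disc) {
  img <- as_gray_image(img)
  mask <- round(unclass(img)) >= cfg$gray_threshold
  if (isTRUE(cfg$open))
    mask <- binary_open(mask, ellipse_kernel(cfg$open_kernel))
  mask
}

#' Screen disc contours
#'
#' Keeps contours with polygonal area within `[area_min_px, area_max_px]`,
#' then removes spinous/ligament remnants: contours that are tall and thin
#' (height/width above `spine_aspect_min`) *and* posterior, i.e. whose
#' centroid lies in the posterior third of the x-range spanned by the
#' accepted vertebrae (or beyond it). Survivors are sorted top to bottom.
#'
#' @param contours List of `ldh_contour` (or a logical mask).
#' @param cfg The `disc` block of [ldh_config()].
#' @param vertebra_xrange Optional `c(xmin, xmax)` of the vertebral column in
#'   px; when `NULL` the posterior gate is skipped.
#' @return Sorted list of surviving contours.
#' @export
screen_disc_contours <- function(contours, cfg = ldh_config()$disc,
                                 vertebra_xrange = NULL) {
  if (is.matrix(contours)) contours <- extract_contours(contours)
  keep <- Filter(function(ct)
    ct$area_px >= cfg$area_min_px && ct$area_px <= cfg$area_max_px, contours)
  if (!is.null(vertebra_xrange)) {
    post_start <- vertebra_xrange[1] + 2 / 3 * diff(vertebra_xrange)
    keep <- Filter(function(ct) {
      tall <- (1 / ct$aspect_ratio) > cfg$spine_aspect_min  # h/w
      !(tall && ct$centroid["x"] >= post_start)
    }, keep)
  }
  keep[order(vapply(keep, function(ct) ct$centroid["y"], numeric(1)))]
}
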