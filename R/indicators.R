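#' Split a disc into protrusion and normal parts
#'
#' The protrusion part consists of the disc pixels strictly posterior to the
#' demarcation line (signed distance > 0); pixels exactly on the line count
#' as normal. The partition is exact: every disc pixel lands in exactly one
#' part. An empty protrusion part is valid (no herniation yet).
#'
#' @param disc An `ldh_contour` or an n x 2 pixel matrix (0-based `(x, y)`).
#' @param line An `ldh_line` (see [demarcation_line()]).
#' @return List with `protrusion` and `normal` pixel matrices.
#' @export
split_disc <- function(disc, line) {
  pix <- disc_pixels(disc)
  s <- signed_distance(line, pix)
  list(protrusion = pix[s > 0, , drop = FALSE],
       normal = pix[s <= 0, , drop = FALSE])
}

disc_pixels <- function(disc) {
  pix <- if (is.list(disc)) disc$pixels else disc
  pix <- matrix(as.numeric(pix), ncol = 2)
  if (nrow(pix) == 0L) stop("disc has no pixels")
  pix
}

#' Protrusion distance
#'
#' Maximum perpendicular distance from the protrusion-part pixels to the
#' demarcation line, converted to millimetres; 0 when the part is empty.
#'
#' @param protrusion_pixels n x 2 pixel matrix (may have zero rows).
#' @param line An `ldh_line`.
#' @param spacing_mm Pixel spacing in mm.
#' @return Distance in mm.
#' @export
protrusion_distance <- function(protrusion_pixels, line, spacing_mm) {
  stopifnot(is.finite(spacing_mm), spacing_mm > 0)
  if (is.null(protrusion_pixels) || nrow(protrusion_pixels) == 0L) return(0)
  max(signed_distance(line, protrusion_pixels)) * spacing_mm
}

#' Compute the five herniation indicators for one disc
#'
#' Returns the indicator vector used by the classifier:
#' * `distance_mm` -- protrusion distance (see [protrusion_distance()]);
#' * `area_mm2` -- protrusion-part pixel count times `spacing^2`;
#' * `length_ratio` -- protrusion distance over the disc's full x-extent
#'   (the segment from the anterior-most to the posterior-most disc pixel);
#' * `area_ratio` -- protrusion-part pixels over whole-disc pixels;
#' * `mean_gray` -- mean image intensity over the whole disc.
#'
#' Doubling the pixel spacing doubles the distance and quadruples the area
#' exactly; the two ratios are dimensionless.
#'
#' @param disc An `ldh_contour` or pixel matrix.
#' @param line An `ldh_line`.
#' @param img Image the mean gray is read from ([gray_image()] or matrix).
#' @param spacing_mm Pixel spacing in mm.
#' @return Named numeric vector
#'   `(distance_mm, area_mm2, length_ratio, area_ratio, mean_gray)`.
#' @export
compute_indicators <- function(disc, line, img, spacing_mm) {
  stopifnot(is.finite(spacing_mm), spacing_mm > 0)
  pix <- disc_pixels(disc)
  parts <- split_disc(pix, line)
  npro <- nrow(parts$protrusion)
  d_mm <- protrusion_distance(parts$protrusion, line, spacing_mm)
  cd_mm <- (diff(range(pix[, 1])) + 1) * spacing_mm
  m <- unclass(img)
  c(distance_mm = d_mm,
    area_mm2 = npro * spacing_mm^2,
    length_ratio = d_mm / cd_mm,
    area_ratio = npro / nrow(pix),
    mean_gray = mean(m[cbind(pix[, 2] + 1, pix[, 1] + 1)]))
}

#' Flag severely degenerated discs by mean gray level
#'
#' A disc is flagged when its mean gray level is strictly below the
#' threshold (default 20): a value of exactly 20 is not flagged.
#'
#' @param mean_grays Numeric vector of per-disc mean gray levels in `[0, 255]`.
#' @param threshold Degeneration threshold (default 20).
#' @return Logical vector.
#' @examples
#' degeneration_flags(c(27.06, 50.83, 55.44, 49.95, 47.41, 24.02, 19.42, 24.56))
#' @export
degeneration_flags <- function(mean_grays, threshold = 20) {
  stopifnot(all(mean_grays >= 0 & mean_grays <= 255), threshold >= 0, threshold <= 255)
  mean_grays < threshold
}
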