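#' Band-pass multithreshold binarization
#'
#' Vertebrae occupy the mid-gray band between the two troughs of the image
#' histogram: foreground pixels are those with intensity in
#' `[threshold_low, threshold_high]`. With `auto_threshold` enabled the upper
#' threshold is taken from the second trough of the Gaussian-smoothed 256-bin
#' histogram (local minima scanned left to right), falling back to the
#' configured defaults when fewer than two troughs exist. A degenerate
#' histogram (single gray level) yields an empty mask with a warning.
#'
#' @param img A [gray_image()] or 0-255 matrix.
#' @param cfg The `vertebra` block of [ldh_config()].
#' @return Logical mask.
#' @export
multithreshold_binarize <- function(img, cfg = ldh_config()$vertebra) {
  img <- as_gray_image(img)
  v <- round(unclass(img))
  lo <- cfg$threshold_low
  hi <- cfg$threshold_high
  if (isTRUE(cfg$auto_threshold)) {
    if (length(unique(as.vector(v))) == 1L) {
      warning("degenerate histogram (single gray level); returning empty mask")
      return(matrix(FALSE, nrow(img), ncol(img)))
    }
    tr <- histogram_troughs(v, sigma = cfg$trough_smooth_sigma %||% 2)
    if (length(tr) >= 2L) hi <- tr[2]
  }
  if (lo > hi) stop("threshold_low must not exceed threshold_high")
  v >= lo & v <= hi
}

# troughs (prominent local minima) of the Gaussian-smoothed 256-bin
# histogram, as gray values scanned left to right; shallow ripples are merged
# into their neighbouring trough so only minima separated by a real peak
# (prominence >= 2% of the histogram maximum) survive
histogram_troughs <- function(v, sigma = 2) {
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  hp <- c(rep(h[1], r), h, rep(h[256], r))  # replicate-pad edges
  sm <- vapply(seq_len(256L), function(i) sum(hp[i:(i + 2 * r)] * k), numeric(1))
  i <- 2:255
  cand <- which(sm[i] <= sm[i - 1] & sm[i] < sm[i + 1]) + 1L  # bin indices
  prom <- 0.02 * max(sm)
  kept <- integer(0)
  for (ci in cand) {
    if (length(kept) == 0L) { kept <- ci; next }
    prev <- kept[length(kept)]
    peak <- max(sm[prev:ci])
    if (peak >= max(sm[prev], sm[ci]) + prom) kept <- c(kept, ci)
    else if (sm[ci] < sm[prev]) kept[length(kept)] <- ci  # deeper ripple wins
  }
  kept - 1L  # bin index -> gray value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen vertebra contours by area, aspect ratio and perimeter
#'
#' Keeps exactly the contours satisfying all three rules: polygonal area
#' within `[area_min_px, area_max_px]`, bounding-box aspect ratio (w/h)
#' within `[aspect_min, aspect_max]`, and perimeter below
#' `perimeter_max_px`. Survivors are sorted top to bottom by centroid y. An
#' empty result is valid (no vertebra found).
#'
#' @param contours List of `ldh_contour` (or a logical mask, which is
#'   extracted first).
#' @param cfg The `vertebra` block of [ldh_config()].
#' @return Sorted list of surviving contours.
#' @export
screen_contours <- function(contours, cfg = ldh_config()$vertebra) {
  if (is.matrix(contours)) contours <- extract_contours(contours)
  keep <- Filter(function(ct) {
    ct$area_px >= cfg$area_min_px && ct$area_px <= cfg$area_max_px &&
      ct$aspect_ratio >= cfg$aspect_min && ct$aspect_ratio <= cfg$aspect_max &&
      ct$perimeter_px < cfg$perimeter_max_px
  }, contours)
  keep[order(vapply(keep, function(ct) ct$centroid["y"], numeric(1)))]
}

#' Detect, screen and localize vertebrae
#'
#' Runs the vertebra stage on a preprocessed image: band-pass binarization,
#' optional adhesion breaking, contour screening, total-least-squares line
#' fitting (the caudal vertebra is the one whose fitted slope magnitude falls
#' in `[caudal_slope_min, caudal_slope_max]`), and corner localization.
#'
#' @param img Preprocessed [gray_image()].
#' @param cfg The `vertebra` block of [ldh_config()].
#' @return List of `ldh_vertebra` objects sorted top to bottom, each with
#'   `contour`, `corners`, `fit_slope`, `fit_intercept`, `is_caudal`.
#' @export
detect_vertebrae <- function(img, cfg = ldh_config()$vertebra) {
  mask <- multithreshold_binarize(img, cfg)
  if (isTRUE(cfg$break_adhesions))
    mask <- break_adhesions(mask, ellipse_kernel(cfg$adhesion_kernel))
  cts <- screen_contours(extract_contours(mask), cfg)
  lapply(cts, function(ct) {
    fl <- fit_line(ct)
    slope <- unname(fl["slope"])
    caudal <- is.finite(slope) &&
      abs(slope) >= cfg$caudal_slope_min && abs(slope) <= cfg$caudal_slope_max
    structure(list(contour = ct,
                   corners = locate_corners(ct, is_caudal = caudal,
                                            mode = cfg$corner_mode %||% "closest",
                                            img_size = c(ncol(img), nrow(img))),
                   fit_slope = slope,
                   fit_intercept = unname(fl["intercept"]),
                   is_caudal = caudal),
              class = "ldh_vertebra")
  })
}

#' Demarcation line between two posterior corners
#'
#' The line through the posterior-inferior corner of the upper vertebra and
#' the posterior-superior corner of the lower vertebra, stored with unit
#' normal coefficients `a x + b y + d = 0` oriented so that positive signed
#' distance is posterior (towards increasing x).
#'
#' @param p_top,p_bottom `c(x, y)` endpoints (0-based pixel coordinates).
#' @return An `ldh_line` with fields `p_top`, `p_bottom`, `a`, `b`, `d`.
#' @export
demarcation_line <- function(p_top, p_bottom) {
  p_top <- as.numeric(p_top[1:2]); p_bottom <- as.numeric(p_bottom[1:2])
  dvec <- p_bottom - p_top
  len <- sqrt(sum(dvec^2))
  if (len < 1e-9) stop("demarcation line endpoints coincide")
  nrm <- c(dvec[2], -dvec[1]) / len
  if (nrm[1] < 0 || (nrm[1] == 0 && nrm[2] < 0)) nrm <- -nrm
  structure(list(p_top = p_top, p_bottom = p_bottom,
                 a = nrm[1], b = nrm[2], d = -sum(nrm * p_top)),
            class = "ldh_line")
}

#' Signed perpendicular distance from points to a demarcation line
#'
#' Positive on the posterior side of the line.
#'
#' @param line An `ldh_line`.
#' @param pts n x 2 matrix of `(x, y)` points.
#' @return Numeric vector of signed distances in px.
#' @export
signed_distance <- function(line, pts) {
  pts <- matrix(pts, ncol = 2)
  line$a * pts[, 1] + line$b * pts[, 2] + line$d
}

#' Demarcation lines between adjacent vertebrae
#'
#' One line per adjacent pair of vertebrae (sorted top to bottom): n
#' vertebrae yield n - 1 lines. Fewer than two vertebrae yield an empty list.
#'
#' @param vertebrae List of `ldh_vertebra` sorted top to bottom.
#' @return List of `ldh_line`; each carries `caudal = TRUE` when its lower
#'   vertebra is the caudal one (discs on such lines are not graded).
#' @export
demarcation_lines <- function(vertebrae) {
  n <- length(vertebrae)
  if (n < 2L) return(list())
  lapply(seq_len(n - 1L), function(i) {
    ln <- demarcation_line(vertebrae[[i]]$corners$posterior_inferior,
                           vertebrae[[i + 1L]]$corners$posterior_superior)
    ln$caudal <- isTRUE(vertebrae[[i + 1L]]$is_caudal)
    ln
  })
}
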