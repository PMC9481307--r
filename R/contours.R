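#' Extract contours of connected components
#'
#' Labels the mask into 8-connected components and derives, for each, its
#' ordered outer boundary (via EBImage contour tracing) together with the
#' features used by the screening rules: polygonal (shoelace) area of the
#' boundary, chain-code perimeter, axis-aligned bounding box, aspect ratio
#' (width/height) and pixel centroid. All coordinates are 0-based `(x, y)`.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return A list of `ldh_contour` objects sorted by component label, each a
#'   list with `points` (m x 2 boundary), `pixels` (n x 2 filled component),
#'   `npix`, `area_px`, `perimeter_px`, `bbox` (`x, y, w, h`),
#'   `aspect_ratio` and `centroid`.
#' @export
extract_contours <- function(mask) {
  lab <- label_components(mask)
  K <- max(lab)
  if (K == 0L) return(list())
  oc <- EBImage::ocontour(EBImage::Image(t(lab)))
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  px <- (idx - 1L) %/% nr  # 0-based x (column)
  py <- (idx - 1L) %% nr   # 0-based y (row)
  byk <- split(seq_along(idx), lab[idx])
  lapply(seq_len(K), function(k) {
    pts <- oc[[k]]
    colnames(pts) <- c("x", "y")
    sel <- byk[[as.character(k)]]
    pix <- cbind(x = px[sel], y = py[sel])
    new_contour(pts, pix)
  })
}

new_contour <- function(points, pixels) {
  n <- nrow(points)
  nxt <- c(seq_len(n)[-1], 1L)
  area <- abs(sum(points[, 1] * points[nxt, 2] - points[nxt, 1] * points[, 2])) / 2
  per <- sum(sqrt(rowSums((points[nxt, , drop = FALSE] - points)^2)))
  xr <- range(pixels[, 1]); yr <- range(pixels[, 2])
  w <- xr[2] - xr[1] + 1; h <- yr[2] - yr[1] + 1
  structure(list(points = points, pixels = pixels, npix = nrow(pixels),
                 area_px = area, perimeter_px = per,
                 bbox = c(x = xr[1], y = yr[1], w = w, h = h),
                 aspect_ratio = w / h,
                 centroid = c(x = mean(pixels[, 1]), y = mean(pixels[, 2]))),
            class = "ldh_contour")
}

#' @export
print.ldh_contour <- function(x, ...) {
  cat(sprintf("<contour> %d px, area %.0f, perimeter %.1f, bbox %dx%d at (%d,%d)\n",
              x$npix, x$area_px, x$perimeter_px,
              x$bbox["w"], x$bbox["h"], x$bbox["x"], x$bbox["y"]))
  invisible(x)
}

#' Total-least-squares line fit of a contour
#'
#' First principal axis of the boundary points, reported as slope `dy/dx`
#' in image coordinates (y down). Vertical principal axes are reported with
#' slope `Inf` and `NA` intercept.
#'
#' @param contour An `ldh_contour` (or any list with a `points` matrix).
#' @return `c(slope, intercept)`.
#' @export
fit_line <- function(contour) {
  pts <- contour$points
  if (nrow(unique(pts)) < 2L) stop("cannot fit a line: all contour points identical")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  if (abs(ev[1]) < 1e-12) return(c(slope = Inf, intercept = NA_real_))
  slope <- ev[2] / ev[1]
  c(slope = slope, intercept = ctr[2] - slope * ctr[1])
}

#' Locate the four anatomical corner points of a vertebra contour
#'
#' Upright vertebrae use, for each corner of the axis-aligned bounding box,
#' the contour point nearest that box corner. The tilted caudal vertebra uses
#' the contour poles (topmost, bottommost, leftmost, rightmost points),
#' relabelled anatomically by their quadrant around the centroid. Posterior is
#' increasing x. Ties are broken by first occurrence in contour order. The
#' alternative `mode = "farthest"` reads the corner rule literally as the
#' contour point farthest from each corner of the picture (which selects the
#' diagonally opposite vertebra corner) and needs `img_size`.
#'
#' @param contour An `ldh_contour`.
#' @param is_caudal Use the pole rule instead of the bounding-box rule.
#' @param mode `"closest"` (default) or `"farthest"`.
#' @param img_size `c(width, height)` in px, only for `mode = "farthest"`.
#' @return Named list of `c(x, y)` points: `anterior_superior`,
#'   `posterior_superior`, `anterior_inferior`, `posterior_inferior`.
#' @export
locate_corners <- function(contour, is_caudal = FALSE,
                           mode = c("closest", "farthest"), img_size = NULL) {
  mode <- match.arg(mode)
  pts <- contour$points
  if (is_caudal) {
    poles <- list(top = pts[which.min(pts[, 2]), ],
                  bottom = pts[which.max(pts[, 2]), ],
                  left = pts[which.min(pts[, 1]), ],
                  right = pts[which.max(pts[, 1]), ])
    ctr <- contour$centroid
    lab <- vapply(poles, function(p) {
      paste0(if (p[1] >= ctr["x"]) "posterior" else "anterior", "_",
             if (p[2] <= ctr["y"]) "superior" else "inferior")
    }, character(1))
    if (anyDuplicated(lab) > 0L) {
      # poles on the centroid axes (degenerate quadrants): label by tilt sign
      sl <- tryCatch(unname(fit_line(contour)["slope"]), error = function(e) 0)
      lab <- if (is.finite(sl) && sl < 0)
        c(top = "posterior_superior", bottom = "anterior_inferior",
          left = "anterior_superior", right = "posterior_inferior")
      else
        c(top = "anterior_superior", bottom = "posterior_inferior",
          left = "anterior_inferior", right = "posterior_superior")
    }
    out <- poles
    names(out) <- lab
    out <- lapply(out, function(p) stats::setNames(as.numeric(p), c("x", "y")))
    return(out[c("anterior_superior", "posterior_superior",
                 "anterior_inferior", "posterior_inferior")])
  }
  bb <- contour$bbox
  anchors <- if (mode == "farthest") {
    if (is.null(img_size)) stop("mode = \"farthest\" needs img_size = c(width, height)")
    W <- img_size[1]; H <- img_size[2]
    # picture corner -> farthest contour point = opposite vertebra corner
    list(anterior_superior = c(W - 1, H - 1), posterior_superior = c(0, H - 1),
         anterior_inferior = c(W - 1, 0), posterior_inferior = c(0, 0))
  } else {
    list(anterior_superior = c(bb["x"], bb["y"]),
         posterior_superior = c(bb["x"] + bb["w"] - 1, bb["y"]),
         anterior_inferior = c(bb["x"], bb["y"] + bb["h"] - 1),
         posterior_inferior = c(bb["x"] + bb["w"] - 1, bb["y"] + bb["h"] - 1))
  }
  pick <- function(anchor, farthest) {
    d2 <- (pts[, 1] - anchor[1])^2 + (pts[, 2] - anchor[2])^2
    i <- if (farthest) which.max(d2) else which.min(d2)
    stats::setNames(as.numeric(pts[i, ]), c("x", "y"))
  }
  lapply(anchors, pick, farthest = (mode == "farthest"))
}
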