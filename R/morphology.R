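#' Elliptical structuring elements
#'
#' Builds the flat elliptical structuring element used throughout the
#' pipeline. Odd sizes contain the pixels whose centres fall inside the
#' inscribed ellipse (a 3x3 element is the 4-connected cross); even sizes are
#' filled boxes, matching the usual raster convention for tiny even elements
#' (the disc stage uses a 2x2 box).
#'
#' @param size Integer scalar or length-2 vector `c(width, height)` in pixels.
#' @return A 0/1 matrix usable as an EBImage kernel.
#' @examples
#' ellipse_kernel(3)  # cross
#' ellipse_kernel(2)  # 2x2 box
#' @export
ellipse_kernel <- function(size) {
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 1L)) stop("kernel size must be >= 1")
  w <- size[1]; h <- size[2]
  if (w %% 2L == 0L || h %% 2L == 0L) {
    # even elements are filled boxes, zero-padded to an odd grid so the
    # element origin is explicit (opening then dilates with the reflection
    # and stays position-exact)
    k <- matrix(0, h + (h %% 2L == 0L), w + (w %% 2L == 0L))
    k[seq_len(h), seq_len(w)] <- 1
    return(k)
  }
  rx <- (w - 1) / 2; ry <- (h - 1) / 2
  dx <- matrix(rep(-rx:rx, each = h), h, w)
  dy <- matrix(rep(-ry:ry, times = w), h, w)
  k <- (dx / max(rx, 0.5))^2 + (dy / max(ry, 0.5))^2 <= 1
  storage.mode(k) <- "double"
  k
}

# 180-degree rotation; opening with an asymmetric element must dilate with the
# reflected kernel to stay position-exact (EBImage does not reflect)
reflect_kernel <- function(k) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]

# binary opening as erosion + reflected dilation on the EBImage side
binary_open <- function(mask, kernel) {
  e <- EBImage::erode(EBImage::Image(t(mask * 1)), kernel)
  d <- EBImage::dilate(e, reflect_kernel(kernel))
  t(EBImage::imageData(d)) > 0.5
}

#' Grayscale morphological opening
#'
#' Erosion followed by dilation with the same flat elliptical element.
#' Removes bright structures smaller than the element (e.g. salt noise beside
#' the vertebrae) and is anti-extensive: the output never exceeds the input.
#'
#' @param img A [gray_image()] or 0-255 matrix.
#' @param kernel Structuring element, see [ellipse_kernel()].
#' @return A [gray_image()] of the same size.
#' @export
gray_open <- function(img, kernel = ellipse_kernel(3)) {
  img <- as_gray_image(img)
  e <- EBImage::erode(to_ebi(img), kernel)
  d <- EBImage::dilate(e, reflect_kernel(kernel))
  from_ebi(d, img)
}

#' 8-connected component labelling
#'
#' Connected components of a binary mask under 8-connectivity. EBImage's
#' `bwlabel()` provides the 4-connected partition; diagonally touching labels
#' are then merged with a union-find pass so that the result is 8-connected.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Integer matrix of labels, 0 = background, components numbered from
#'   1 in scan order.
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  storage.mode(lab) <- "integer"
  K <- max(lab)
  if (K > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour pairs (both diagonals)
    a <- c(lab[-nr, -nc], lab[-nr, -1])
    b <- c(lab[-1, -1], lab[-1, -nc])
    sel <- a > 0L & b > 0L & a != b
    parent <- seq_len(K)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(K), find, integer(1))
      relab <- match(root, sort(unique(root)))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  lab
}

#' Break vertebral adhesions by binary opening
#'
#' Erosion followed by dilation with the same elliptical element disconnects
#' regions joined by bridges thinner than the element while approximately
#' preserving large solid shapes. The operation never merges distinct
#' components (it is anti-extensive); it can remove sub-kernel specks.
#'
#' @param mask Logical matrix.
#' @param kernel Structuring element (default 3x3 ellipse).
#' @return Logical matrix.
#' @export
break_adhesions <- function(mask, kernel = ellipse_kernel(3)) {
  stopifnot(is.matrix(mask))
  binary_open(mask > 0, kernel)
}
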