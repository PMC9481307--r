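#' 8-bit grayscale image with optional physical pixel spacing
#'
#' The package's canonical image container: a numeric matrix of intensities in
#' `[0, 255]` with rows running top to bottom (y) and columns left to right
#' (x), plus an optional isotropic pixel spacing in millimetres. Pixel
#' coordinates reported by the package are 0-based `(x, y)` with the origin at
#' the top-left corner; the pixel at `(x, y)` is `img[y + 1, x + 1]`.
#' Posterior anatomy is towards increasing `x` (image right).
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param pixel_spacing_mm Isotropic pixel edge length in mm (`NA` if unknown).
#' @return A `gray_image` object (matrix subclass).
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), pixel_spacing_mm = 0.5)
#' pixel_spacing(img)
#' @export
gray_image <- function(pixels, pixel_spacing_mm = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255] with no missing values")
  if (!is.na(pixel_spacing_mm) && pixel_spacing_mm <= 0)
    stop("`pixel_spacing_mm` must be positive")
  structure(pixels,
            pixel_spacing_mm = as.numeric(pixel_spacing_mm),
            class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param img A `gray_image` (or plain matrix, for which `NA` is returned).
#' @export
pixel_spacing <- function(img) {
  sp <- attr(img, "pixel_spacing_mm")
  if (is.null(sp)) NA_real_ else sp
}

#' @rdname gray_image
#' @param value New spacing in mm.
#' @export
`pixel_spacing<-` <- function(img, value) {
  stopifnot(is.na(value) || value > 0)
  attr(img, "pixel_spacing_mm") <- as.numeric(value)
  img
}

#' @export
print.gray_image <- function(x, ...) {
  sp <- pixel_spacing(x)
  cat(sprintf("<gray_image> %d x %d px, spacing %s mm, range [%g, %g]\n",
              ncol(x), nrow(x), if (is.na(sp)) "unknown" else format(sp),
              min(x), max(x)))
  invisible(x)
}

# rebuild a gray_image around transformed pixels, keeping spacing
restamp <- function(pixels, template) {
  gray_image(pixels, pixel_spacing(template))
}

# coerce matrix-like input (keeps an existing gray_image untouched)
as_gray_image <- function(x, pixel_spacing_mm = NA_real_) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, pixel_spacing_mm)
}

# clip + round to the 8-bit grid (round half to even, as documented)
quantize8 <- function(x) round(pmin(pmax(x, 0), 255))

# EBImage bridge: EBImage stores images as [x, y] in [0, 1]
to_ebi <- function(img) EBImage::Image(t(unclass(img)) / 255)
from_ebi <- function(e, template) restamp(quantize8(t(EBImage::imageData(e)) * 255), template)

#' Read and write 8-bit grayscale PNG images
#'
#' Round-trips are lossless for integer-valued images. Color PNGs are
#' converted to grayscale by channel averaging.
#'
#' @param path File path.
#' @param pixel_spacing_mm Spacing to stamp on the image (PNG carries none).
#' @return `read_gray_png`: a [gray_image()]; `write_gray_png`: `path`, invisibly.
#' @export
read_gray_png <- function(path, pixel_spacing_mm = NA_real_) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  gray_image(quantize8(a * 255), pixel_spacing_mm)
}

#' @rdname read_gray_png
#' @param img A [gray_image()] or 0-255 matrix.
#' @export
write_gray_png <- function(img, path) {
  img <- as_gray_image(img)
  ok <- try(png::writePNG(unclass(img) / 255, target = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write image: ", path)
  invisible(path)
}
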