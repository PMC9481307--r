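#' Power-law (gamma) intensity transform
#'
#' Applies `s = c * r^gamma` with intensities normalized to `[0, 1]` before
#' the power law and rescaled to `[0, 255]` afterwards. `gamma < 1` with
#' `c = 1` brightens dark tissue, which helps separate low-signal targets
#' from a dark background; `gamma = 1`, `c = 1` is the identity. Output is
#' clipped to range and rounded half-to-even to the 8-bit grid.
#'
#' @param img A [gray_image()] or 0-255 matrix.
#' @param gamma Positive exponent (default 0.5).
#' @param c Multiplicative constant (default 1).
#' @return A [gray_image()].
#' @export
gamma_transform <- function(img, gamma = 0.5, c = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a positive number")
  img <- as_gray_image(img)
  s <- pmin(pmax(c * (unclass(img) / 255)^gamma, 0), 1)
  restamp(quantize8(s * 255), img)
}

#' Fuzzy contrast intensification
#'
#' S-shaped remapping about mid-gray using the classical fuzzy
#' intensification operator with a linear membership `mu = r / 255`:
#' `mu' = 2 mu^2` for `mu <= 0.5`, else `1 - 2 (1 - mu)^2`, mapped back to
#' gray levels. Values near mid-gray are pushed towards the extremes, which
#' widens mid-range contrast; saturation ("over-exposure") near the ends of
#' the range is permitted and expected.
#'
#' @param img A [gray_image()] or 0-255 matrix.
#' @return A [gray_image()].
#' @export
fuzzy_enhance <- function(img) {
  img <- as_gray_image(img)
  mu <- unclass(img) / 255
  out <- ifelse(mu <= 0.5, 2 * mu^2, 1 - 2 * (1 - mu)^2)
  restamp(quantize8(out * 255), img)
}

#' Global histogram equalization
#'
#' Standard CDF-based equalization on 256 bins with the conventional
#' normalization `s = round(255 * (cdf(r) - cdf_min) / (N - cdf_min))`, a
#' monotone intensity mapping. A constant image is returned unchanged, and an
#' image whose histogram is already uniform maps to itself up to one gray
#' level of quantization.
#'
#' @param img A [gray_image()] or 0-255 matrix.
#' @return A [gray_image()].
#' @export
equalize_hist <- function(img) {
  img <- as_gray_image(img)
  v <- as.integer(round(unclass(img)))
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0L)[1]]
  n <- length(v)
  if (n == cdf_min) return(img)  # single gray level: nothing to spread
  lut <- quantize8(255 * (cdf - cdf_min) / (n - cdf_min))
  restamp(matrix(lut[v + 1L], nrow(img), ncol(img)), img)
}

#' Full preprocessing chain
#'
#' Composition of the four preprocessing steps in fixed order -- grayscale
#' opening, gamma transform, fuzzy intensification, histogram equalization --
#' each individually toggleable through the config. With every step disabled
#' the input is returned unchanged. The chain is deterministic.
#'
#' @param img A [gray_image()] or 0-255 matrix.
#' @param config The `preprocess` block of [ldh_config()].
#' @return A [gray_image()].
#' @examples
#' img <- gray_image(matrix(rep(c(40, 160), each = 128), 16, 16))
#' out <- preprocess(img, ldh_config()$preprocess)
#' @export
preprocess <- function(img, config = ldh_config()$preprocess) {
  img <- as_gray_image(img)
  if (isTRUE(config$open))
    img <- gray_open(img, ellipse_kernel(config$open_kernel))
  if (isTRUE(config$gamma_enabled))
    img <- gamma_transform(img, config$gamma, config$gamma_c)
  if (isTRUE(config$fuzzy))
    img <- fuzzy_enhance(img)
  if (isTRUE(config$equalize))
    img <- equalize_hist(img)
  img
}
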