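#' Write a phantom case to disk as a fixture
#'
#' Writes `image.png` (the 8-bit image, noisy if the spec asked for noise),
#' per-structure mask PNGs under `masks/`, and `manifest.json` holding the
#' pixel spacing, per-disc true grades and indicator vectors, degeneration
#' flags and the canal state. Everything round-trips losslessly through
#' [read_fixture()].
#'
#' @param phantom An `ldh_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
write_fixture <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ldh_phantom"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  tr <- phantom$truth
  write_gray_png(phantom$image, file.path(dir, "image.png"))
  for (i in seq_along(tr$vertebra_masks))
    write_gray_png(tr$vertebra_masks[[i]] * 255,
                   file.path(dir, "masks", sprintf("vertebra_%02d.png", i)))
  for (i in seq_along(tr$disc_masks))
    write_gray_png(tr$disc_masks[[i]] * 255,
                   file.path(dir, "masks", sprintf("disc_%02d.png", i)))
  write_gray_png(tr$canal_mask * 255, file.path(dir, "masks", "canal.png"))
  manifest <- list(
    pixel_spacing_mm = tr$spec$pixel_spacing_mm,
    n_vertebrae = tr$spec$n_vertebrae,
    noise_sigma = tr$spec$noise_sigma,
    rng_seed = tr$spec$rng_seed,
    canal = list(interrupted = tr$spec$canal_interrupted),
    lines = lapply(tr$lines, function(ln)
      list(p_top = ln$p_top, p_bottom = ln$p_bottom, caudal = isTRUE(ln$caudal))),
    discs = lapply(seq_along(tr$disc_masks), function(i) list(
      index = i,
      true_class = tr$true_class[i],
      caudal_adjacent = tr$caudal_adjacent[i],
      degenerated = tr$degenerated[i],
      indicators = as.list(tr$indicators[[i]]))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `image` (a [gray_image()] stamped with the manifest's
#'   spacing), `manifest`, and `masks` (`vertebrae`, `discs`, `canal` as
#'   logical matrices).
#' @export
read_fixture <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  img <- read_gray_png(file.path(dir, "image.png"),
                       pixel_spacing_mm = manifest$pixel_spacing_mm)
  read_mask <- function(p) unclass(read_gray_png(p)) > 127
  nv <- manifest$n_vertebrae
  masks <- list(
    vertebrae = lapply(seq_len(nv), function(i)
      read_mask(file.path(dir, "masks", sprintf("vertebra_%02d.png", i)))),
    discs = lapply(seq_len(nv - 1L), function(i)
      read_mask(file.path(dir, "masks", sprintf("disc_%02d.png", i)))),
    canal = read_mask(file.path(dir, "masks", "canal.png")))
  list(image = img, manifest = manifest, masks = masks)
}
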