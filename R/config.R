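#' Pipeline configuration
#'
#' Every threshold of the pipeline lives in one nested list, overridable from
#' a YAML file via [read_config()]. Blocks: `preprocess` (step toggles,
#' opening kernel, gamma), `vertebra` (band-pass thresholds 105/205,
#' screening ranges 3000--6000 px area, 0.6--1.4 aspect, perimeter < 400 px,
#' caudal slope band 0.1--1), `disc` (gray threshold 50, 2x2 opening,
#' 100--2000 px area, spinous aspect rule), `canal` (search window and
#' coverage), `indicators` (gray source, degeneration threshold 20, "tiny
#' protrusion" cutoffs) and `table1` (the grade-range cut points, see
#' [class_ranges()]). `pixel_spacing_mm` is the fallback spacing used when
#' the image carries none.
#'
#' @return Nested configuration list.
#' @export
ldh_config <- function() {
  list(
    pixel_spacing_mm = 0.5,
    preprocess = list(open = TRUE, open_kernel = 3,
                      gamma_enabled = TRUE, gamma = 0.5, gamma_c = 1,
                      fuzzy = TRUE, equalize = TRUE),
    vertebra = list(threshold_low = 105, threshold_high = 205,
                    auto_threshold = FALSE, trough_smooth_sigma = 2,
                    break_adhesions = TRUE, adhesion_kernel = 3,
                    area_min_px = 3000, area_max_px = 6000,
                    aspect_min = 0.6, aspect_max = 1.4,
                    perimeter_max_px = 400,
                    caudal_slope_min = 0.1, caudal_slope_max = 1.0,
                    corner_mode = "closest"),
    disc = list(gray_threshold = 50, open = TRUE, open_kernel = 2,
                area_min_px = 100, area_max_px = 2000,
                spine_aspect_min = 0.8),
    canal = list(x_offset_min_px = 2, x_offset_max_px = 40,
                 min_vertical_coverage = 0.8),
    indicators = list(gray_source = "preprocessed",
                      degeneration_threshold = 20,
                      normal_area_mm2 = 10, normal_distance_mm = 1),
    table1 = list(distance = c(1, 5, 10), area = c(10, 100, 200),
                  length_ratio = c(0.01, 0.1, 0.2),
                  area_ratio = c(0.01, 0.1, 0.2),
                  gray_extrusion_max = 15, gray_bulge_min = 35)
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' Keys present in the file override the matching defaults; everything else
#' keeps its default value. Unknown keys are rejected to catch typos.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  user <- yaml::read_yaml(path)
  merge_config(ldh_config(), user, keypath = "")
}

merge_config <- function(base, user, keypath) {
  if (!is.list(user)) return(user)
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown config key: ", sub("^\\.", "", paste0(keypath, ".", k)))
    base[[k]] <- if (is.list(base[[k]])) merge_config(base[[k]], user[[k]], paste0(keypath, ".", k))
                 else user[[k]]
  }
  base
}

#' Configuration for the synthetic-phantom protocol
#'
#' The phantom renders calibrated intensities (vertebrae at 150, discs and
#' canal above the disc threshold, background well below it) with additive
#' Gaussian noise, so the contrast-enhancement chain and the cleanup
#' morphology are unnecessary and would only bias the pixel-exact landmarks
#' the recovery tests measure (grayscale opening clips the single-pixel
#' protrusion apex; corner erosion shifts the demarcation line; the
#' disc-stage opening shaves single-pixel steps off the bump silhouette).
#' This protocol therefore disables the preprocessing steps, the
#' vertebra-stage adhesion breaking and the disc-stage opening; every
#' disabled step is exercised by its own unit tests on fixtures built for
#' it.
#'
#' @return Configuration list (see [ldh_config()]).
#' @export
phantom_pipeline_config <- function() {
  cfg <- ldh_config()
  cfg$preprocess$open <- FALSE
  cfg$preprocess$gamma_enabled <- FALSE
  cfg$preprocess$fuzzy <- FALSE
  cfg$preprocess$equalize <- FALSE
  cfg$vertebra$break_adhesions <- FALSE
  cfg$disc$open <- FALSE
  cfg
}

ranges_from_config <- function(config) {
  t1 <- config$table1
  class_ranges(distance = t1$distance, area = t1$area,
               length_ratio = t1$length_ratio, area_ratio = t1$area_ratio,
               gray_extrusion_max = t1$gray_extrusion_max,
               gray_bulge_min = t1$gray_bulge_min)
}
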