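#' Specification of a synthetic sagittal spine phantom
#'
#' Describes a mid-sagittal T2-like spine image: a vertical column of bright
#' rectangular vertebrae (the bottom, caudal one tilted), bright elliptical
#' discs in the gaps with optional posterior protrusion bumps of controlled
#' distance and area, a bright posterior spinal-canal band (optionally
#' interrupted), smooth background tissue texture and additive Gaussian
#' noise. Identical spec and seed give bit-identical output.
#'
#' Protrusion bumps are half-ellipses attached to the disc's posterior edge
#' at the demarcation line, parameterized so distance and area are
#' independently controllable; distances are quantized to the pixel grid
#' (0.5 mm at the default spacing) so the rendered apex lands exactly at the
#' requested distance.
#'
#' @param image_height_px,image_width_px Canvas size (defaults 700 x 448).
#' @param n_vertebrae Number of vertebrae (>= 2, default 6); there are
#'   `n_vertebrae - 1` discs and the last one neighbours the caudal
#'   vertebra.
#' @param vertebra_intensity,canal_intensity,background_intensity Gray
#'   levels in `[0, 255]`.
#' @param disc_intensity Per-disc gray level (recycled to `n_vertebrae - 1`).
#' @param canal_interrupted Interrupt the canal band by a gap of
#'   `canal_gap_frac` of the column height.
#' @param protrusion_distance_mm,protrusion_area_mm2 Per-disc bump size
#'   (recycled); 0 means no bump.
#' @param caudal_tilt_deg Tilt of the bottom vertebra (default 15).
#' @param pixel_spacing_mm Isotropic spacing (default 0.5).
#' @param noise_sigma Std. dev. of additive Gaussian noise (default 0).
#' @param rng_seed Seed for the noise field.
#' @param vertebra_width_px,vertebra_height_px,disc_gap_px,caudal_gap_px,
#'   anterior_x_px,disc_semi_height_px,canal_offset_px,canal_width_px,
#'   corner_radius_px,canal_gap_frac Geometry knobs (sized so the rendered
#'   structures fall inside the default screening ranges at 0.5 mm/px).
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(image_height_px = 700, image_width_px = 448,
                         n_vertebrae = 6,
                         vertebra_intensity = 150,
                         disc_intensity = 215,
                         canal_intensity = 180,
                         canal_interrupted = FALSE,
                         protrusion_distance_mm = 0,
                         protrusion_area_mm2 = 0,
                         caudal_tilt_deg = 15,
                         pixel_spacing_mm = 0.5,
                         noise_sigma = 0,
                         rng_seed = 1L,
                         vertebra_width_px = 70, vertebra_height_px = 55,
                         disc_gap_px = 64, caudal_gap_px = 34,
                         anterior_x_px = 145, disc_semi_height_px = 9,
                         canal_offset_px = 30, canal_width_px = 15,
                         corner_radius_px = 0, canal_gap_frac = 0.2,
                         background_intensity = 30) {
  n <- as.integer(n_vertebrae)
  if (n < 2L) stop("n_vertebrae must be >= 2")
  nd <- n - 1L
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_vertebrae = n,
    vertebra_intensity = vertebra_intensity,
    disc_intensity = rep_len(disc_intensity, nd),
    canal_intensity = canal_intensity,
    canal_interrupted = isTRUE(canal_interrupted),
    protrusion_distance_mm = rep_len(protrusion_distance_mm, nd),
    protrusion_area_mm2 = rep_len(protrusion_area_mm2, nd),
    caudal_tilt_deg = caudal_tilt_deg,
    pixel_spacing_mm = pixel_spacing_mm,
    noise_sigma = noise_sigma,
    rng_seed = as.integer(rng_seed),
    vertebra_width_px = as.integer(vertebra_width_px),
    vertebra_height_px = as.integer(vertebra_height_px),
    disc_gap_px = as.integer(disc_gap_px),
    caudal_gap_px = as.integer(caudal_gap_px),
    anterior_x_px = as.integer(anterior_x_px),
    disc_semi_height_px = disc_semi_height_px,
    canal_offset_px = as.integer(canal_offset_px),
    canal_width_px = as.integer(canal_width_px),
    corner_radius_px = corner_radius_px,
    canal_gap_frac = canal_gap_frac,
    background_intensity = background_intensity)
  ints <- c(spec$vertebra_intensity, spec$disc_intensity, spec$canal_intensity,
            spec$background_intensity)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")
  if (any(spec$protrusion_distance_mm < 0) || any(spec$protrusion_area_mm2 < 0))
    stop("protrusion parameters must be non-negative")
  if (any((spec$protrusion_distance_mm > 0) != (spec$protrusion_area_mm2 > 0)))
    stop("protrusion distance and area must be zero or positive together")
  if (spec$pixel_spacing_mm <= 0) stop("pixel_spacing_mm must be positive")
  if (spec$noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(spec, class = "phantom_spec")
}

# per-grade bump/intensity presets under the default geometry; the extrusion
# disc is rendered dimmer (degenerating) but still above the disc threshold
phantom_disc_presets <- function() {
  list(normal = list(distance_mm = 0, area_mm2 = 0, intensity = 215),
       bulge = list(distance_mm = 3, area_mm2 = 40, intensity = 215),
       protrusion = list(distance_mm = 7, area_mm2 = 150, intensity = 210),
       extrusion = list(distance_mm = 12, area_mm2 = 250, intensity = 70))
}

#' Phantom spec with discs drawn from the four herniation grades
#'
#' Builds a [phantom_spec()] whose graded discs (all but the caudal-adjacent
#' one, which stays normal and is not graded by the pipeline) are sampled
#' uniformly from the four grades, with per-grade bump parameters jittered
#' on the pixel grid and the caudal tilt and tissue intensities jittered
#' within their working bands. This is the study condition used by the
#' recovery experiments.
#'
#' @param seed Integer seed driving every random choice.
#' @param noise_sigma Additive noise level (default 0).
#' @param classes Optional character vector of grades for the graded discs
#'   (recycled); random when `NULL`.
#' @param canal_interrupted Render the canal band with a gap.
#' @return A `phantom_spec` whose `disc_grades` attribute records the
#'   intended grade of every disc.
#' @export
random_phantom_spec <- function(seed, noise_sigma = 0, classes = NULL,
                                canal_interrupted = FALSE) {
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    n <- 6L
    nd <- n - 1L
    grades <- if (is.null(classes)) sample(ldh_grades, nd - 1L, replace = TRUE)
              else rep_len(classes, nd - 1L)
    grades <- c(grades, "normal")  # caudal-adjacent disc stays normal
    pre <- phantom_disc_presets()
    dist <- area <- numeric(nd)
    inten <- numeric(nd)
    for (i in seq_len(nd)) {
      g <- grades[i]
      dist[i] <- switch(g, normal = 0,
                        bulge = sample(seq(2, 4.5, by = 0.5), 1),
                        protrusion = sample(seq(5.5, 9, by = 0.5), 1),
                        extrusion = sample(seq(10.5, 13.5, by = 0.5), 1))
      # largest area a bump of this distance can hold inside the disc gap
      cap <- bump_capacity(round(dist[i] / 0.5), h_max = 28) * 0.25
      area[i] <- switch(g, normal = 0,
                        bulge = stats::runif(1, 20, min(60, cap)),
                        protrusion = stats::runif(1, 110, min(190, cap)),
                        extrusion = stats::runif(1, 210, min(240, cap)))
      inten[i] <- if (g == "extrusion") stats::runif(1, 62, 80)
                  else pre[[g]]$intensity + stats::runif(1, -6, 8)
    }
    sp <- phantom_spec(n_vertebrae = n,
                       vertebra_intensity = stats::runif(1, 140, 160),
                       disc_intensity = inten,
                       protrusion_distance_mm = dist,
                       protrusion_area_mm2 = area,
                       caudal_tilt_deg = stats::runif(1, 12, 22),
                       canal_interrupted = canal_interrupted,
                       noise_sigma = noise_sigma,
                       rng_seed = sample.int(2147483646L, 1))
    attr(sp, "disc_grades") <- grades
    sp
  })
}

#' Render a phantom image with exact ground truth
#'
#' Rasterizes the spec into an 8-bit image plus per-structure binary masks,
#' the true demarcation lines, and per-disc ground-truth indicator vectors
#' (computed on the noiseless render, so each disc's mean gray equals its
#' spec intensity exactly). Masks match the rendered shapes exactly, before
#' noise. The true grade of each disc is whatever [classify_herniation()]
#' assigns to its true indicator vector. Specs whose shapes would overlap or
#' leave the canvas are rejected.
#'
#' @param spec A [phantom_spec()].
#' @return An `ldh_phantom` list: `image` ([gray_image()], noisy if
#'   requested), `clean` (noiseless image), and `truth` with
#'   `vertebra_masks`, `disc_masks`, `canal_mask`, `lines`, `indicators`,
#'   `true_class`, `degenerated`, `caudal_adjacent`, `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_vertebrae = 4))
#' ph$truth$true_class
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_height_px; W <- spec$image_width_px
  n <- spec$n_vertebrae; nd <- n - 1L
  sp_mm <- spec$pixel_spacing_mm
  vw <- spec$vertebra_width_px; vh <- spec$vertebra_height_px
  ax <- spec$anterior_x_px
  px_post <- ax + vw - 1L                    # posterior vertebra edge (0-based)
  theta <- spec$caudal_tilt_deg * pi / 180
  cb_h <- vw * abs(sin(theta)) + vh * cos(theta)  # caudal bounding height
  total <- (n - 1L) * vh + (n - 2L) * spec$disc_gap_px + spec$caudal_gap_px + ceiling(cb_h)
  if (total > H) stop("phantom exceeds image bounds: column height ", total, " > ", H)
  top <- max(5L, (H - total) %/% 2L)

  X <- matrix(rep(0:(W - 1L), each = H), H, W)
  Y <- matrix(rep(0:(H - 1L), times = W), H, W)

  # straight vertebrae
  v_top <- top + (seq_len(n - 1L) - 1L) * (vh + spec$disc_gap_px)
  v_bot <- v_top + vh - 1L
  vmasks <- vector("list", n)
  r <- spec$corner_radius_px
  for (i in seq_len(n - 1L)) {
    m <- X >= ax & X <= px_post & Y >= v_top[i] & Y <= v_bot[i]
    if (r > 0) {
      for (cx in c(ax + r, px_post - r)) for (cy in c(v_top[i] + r, v_bot[i] - r)) {
        corner <- (if (cx == ax + r) X < ax + r else X > px_post - r) &
                  (if (cy == v_top[i] + r) Y < v_top[i] + r else Y > v_bot[i] - r)
        m[corner & ((X - cx)^2 + (Y - cy)^2 > r^2)] <- FALSE
      }
    }
    vmasks[[i]] <- m
  }

  # caudal vertebra: rectangle rotated by theta (posterior side down)
  ccx <- ax + (vw - 1) / 2
  ccy <- v_bot[n - 1L] + spec$caudal_gap_px + cb_h / 2
  u <- (X - ccx) * cos(theta) + (Y - ccy) * sin(theta)
  w2 <- -(X - ccx) * sin(theta) + (Y - ccy) * cos(theta)
  vmasks[[n]] <- abs(u) <= (vw - 1) / 2 & abs(w2) <= (vh - 1) / 2
  caudal_bot <- ceiling(ccy + cb_h / 2)

  # analytic caudal corners (posterior = +x in the rect frame)
  rot <- function(dx, dy) c(ccx + dx * cos(theta) - dy * sin(theta),
                            ccy + dx * sin(theta) + dy * cos(theta))
  caudal_ps <- rot((vw - 1) / 2, -(vh - 1) / 2)

  # true demarcation lines (vertical for straight pairs, slanted for caudal)
  lines <- vector("list", nd)
  for (i in seq_len(nd)) {
    lines[[i]] <- if (i < nd)
      demarcation_line(c(px_post, v_bot[i]), c(px_post, v_top[i + 1L]))
    else demarcation_line(c(px_post, v_bot[n - 1L]), caudal_ps)
    lines[[i]]$caudal <- (i == nd)
  }

  # discs: posterior-touching ellipse plus optional posterior bump
  a_semi <- (vw - 6) / 2          # disc slightly inset from the vertebra width
  b_semi <- spec$disc_semi_height_px
  dmasks <- vector("list", nd)
  d_px <- round(spec$protrusion_distance_mm / sp_mm)
  a_px <- spec$protrusion_area_mm2 / sp_mm^2
  for (i in seq_len(nd)) {
    dcy <- if (i < nd) (v_bot[i] + v_top[i + 1L]) / 2
           else v_bot[n - 1L] + 11
    ln <- lines[[i]]
    # posterior edge of the ellipse sits on the demarcation line at disc height
    lx <- if (abs(ln$b) < 1e-12) -ln$d / ln$a else (-ln$d - ln$b * dcy) / ln$a
    dcx <- floor(lx) - a_semi
    # lens profile with a 2-px-thick floor so the posterior apex stays
    # connected to the bump and survives the disc-stage 2x2 opening
    xr <- abs(X - dcx) / a_semi
    m <- xr <= 1 &
      abs(Y - dcy) <= pmax(1, b_semi * sqrt(pmax(0, 1 - xr^2)))
    if (d_px[i] > 0) {
      if (a_px[i] <= 0) stop("disc ", i, ": positive distance needs positive area")
      hh <- solve_bump_height(d_px[i], a_px[i], frac = dcy - floor(dcy))
      s <- ln$a * X + ln$b * Y + ln$d
      tt <- -ln$b * (X - dcx) + ln$a * (Y - dcy)  # tangential offset from disc centre
      m <- m | (s > 0 & s <= d_px[i] &
                  abs(tt) <= pmax(1, hh * sqrt(pmax(0, 1 - (s / d_px[i])^2))))
    }
    if (d_px[i] > 0 && i < nd) {
      bump_rows <- range(Y[m & X > px_post])
      if (bump_rows[1] < v_bot[i] + 2L || bump_rows[2] > v_top[i + 1L] - 2L)
        stop("disc ", i, ": protrusion bump reaches the neighbouring vertebra; ",
             "reduce its area or enlarge disc_gap_px")
    }
    dmasks[[i]] <- m
  }

  # spinal canal band
  c0 <- px_post + spec$canal_offset_px
  c1 <- c0 + spec$canal_width_px - 1L
  if (c1 >= W) stop("canal exceeds image bounds")
  cm <- X >= c0 & X <= c1 & Y >= top & Y <= caudal_bot
  if (spec$canal_interrupted) {
    gap <- round(spec$canal_gap_frac * (caudal_bot - top + 1))
    g0 <- top + ((caudal_bot - top + 1) - gap) %/% 2
    cm[Y >= g0 & Y < g0 + gap] <- FALSE
  }

  all_masks <- c(vmasks, dmasks, list(cm))
  stack <- Reduce(`+`, lapply(all_masks, function(m) m * 1L))
  if (max(stack) > 1L) stop("phantom shapes overlap; adjust the spec geometry")

  # compose: textured background, then structures, then noise
  img <- spec$background_intensity +
    8 * sin(2 * pi * Y / 97) * sin(2 * pi * X / 113)
  for (i in seq_len(n)) img[vmasks[[i]]] <- spec$vertebra_intensity
  for (i in seq_len(nd)) img[dmasks[[i]]] <- spec$disc_intensity[i]
  img[cm] <- spec$canal_intensity
  clean <- gray_image(quantize8(img), sp_mm)
  noisy <- if (spec$noise_sigma > 0) {
    withr::with_seed(spec$rng_seed, {
      gray_image(quantize8(unclass(clean) +
                             matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)), sp_mm)
    })
  } else clean

  # ground-truth indicators on the noiseless render
  mask_pixels <- function(m) {
    idx <- which(m)
    cbind(x = (idx - 1L) %/% H, y = (idx - 1L) %% H)
  }
  indicators <- lapply(seq_len(nd), function(i)
    compute_indicators(mask_pixels(dmasks[[i]]), lines[[i]], clean, sp_mm))
  true_class <- vapply(indicators, function(v) classify_herniation(v)$label, character(1))
  truth <- list(vertebra_masks = vmasks, disc_masks = dmasks, canal_mask = cm,
                lines = lines, indicators = indicators, true_class = true_class,
                degenerated = vapply(indicators, function(v)
                  unname(v["mean_gray"]) < 20, logical(1)),
                caudal_adjacent = seq_len(nd) == nd,
                spec = spec)
  structure(list(image = noisy, clean = clean, truth = truth), class = "ldh_phantom")
}

# pixel count of a rasterized bump of x-extent d_px and half-height h (row
# counts for a half-integer disc centre); used to bound feasible bump areas
bump_capacity <- function(d_px, h_max) {
  if (d_px < 1) return(0)
  s <- seq_len(d_px)
  w <- pmax(1, h_max * sqrt(pmax(0, 1 - (s / d_px)^2)))
  sum(2 * floor(w + 0.5))
}

# smallest half-ellipse height whose rasterized bump (thickness floor 1 px)
# has a pixel count nearest the requested area; `frac` is the fractional row
# offset of the disc centre (row counts differ between integer and
# half-integer centres)
solve_bump_height <- function(d_px, area_px, frac = 0.5) {
  count <- function(h) {
    s <- seq_len(d_px)
    w <- pmax(1, h * sqrt(pmax(0, 1 - (s / d_px)^2)))
    if (abs(frac - 0.5) < 1e-9) sum(2 * floor(w + 0.5)) else sum(2 * floor(w) + 1)
  }
  lo <- 0.5; hi <- max(4, 4 * area_px / d_px)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (count(mid) < area_px) lo <- mid else hi <- mid
  }
  if (abs(count(lo) - area_px) < abs(count(hi) - area_px)) lo else hi
}

#' @export
print.ldh_phantom <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("<phantom> %d x %d px, %d vertebrae, %d discs [%s], canal %s\n",
              ncol(x$image), nrow(x$image), length(tr$vertebra_masks),
              length(tr$disc_masks), paste(tr$true_class, collapse = ", "),
              if (tr$spec$canal_interrupted) "interrupted" else "continuous"))
  invisible(x)
}
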