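#' Indicator ranges for the three herniation grades
#'
#' The per-indicator intervals defining bulge, protrusion and extrusion. The
#' four geometric indicators use increasing-severity cut points made disjoint
#' with the half-open convention `[low, high)`: values below the first cut
#' vote for no grade, `[c1, c2)` votes bulge, `[c2, c3)` protrusion and
#' `>= c3` extrusion. Mean gray decreases with severity: above
#' `gray_bulge_min` votes bulge, strictly below `gray_extrusion_max` votes
#' extrusion, and the closed interval between them (both boundaries
#' included) votes protrusion -- so every boundary value belongs to exactly
#' one grade. Defaults: distance (mm) cuts 1/5/10; area (mm^2) 10/100/200;
#' length ratio and area ratio 0.01/0.1/0.2; mean gray bulge > 35,
#' protrusion 15--35, extrusion < 15.
#'
#' @param distance,area,length_ratio,area_ratio Length-3 increasing cut
#'   points for the geometric indicators.
#' @param gray_extrusion_max,gray_bulge_min Mean-gray boundaries.
#' @return A `ldh_ranges` list.
#' @export
class_ranges <- function(distance = c(1, 5, 10),
                         area = c(10, 100, 200),
                         length_ratio = c(0.01, 0.1, 0.2),
                         area_ratio = c(0.01, 0.1, 0.2),
                         gray_extrusion_max = 15,
                         gray_bulge_min = 35) {
  for (cuts in list(distance, area, length_ratio, area_ratio))
    if (length(cuts) != 3L || is.unsorted(cuts, strictly = TRUE))
      stop("geometric cut points must be three strictly increasing values")
  if (gray_extrusion_max >= gray_bulge_min)
    stop("gray_extrusion_max must be below gray_bulge_min")
  structure(list(distance = distance, area = area,
                 length_ratio = length_ratio, area_ratio = area_ratio,
                 gray_extrusion_max = gray_extrusion_max,
                 gray_bulge_min = gray_bulge_min),
            class = "ldh_ranges")
}

ldh_grades <- c("normal", "bulge", "protrusion", "extrusion")

vote_increasing <- function(x, cuts) {
  if (x < cuts[1]) "none"
  else if (x < cuts[2]) "bulge"
  else if (x < cuts[3]) "protrusion"
  else "extrusion"
}

vote_gray <- function(x, ranges) {
  if (x > ranges$gray_bulge_min) "bulge"
  else if (x >= ranges$gray_extrusion_max) "protrusion"
  else "extrusion"
}

#' Per-grade votes of an indicator vector
#'
#' Each of the five indicators votes for at most one grade (geometric
#' indicators below the bulge cut vote for none; mean gray always votes).
#'
#' @param v Indicator vector in the order
#'   `(distance_mm, area_mm2, length_ratio, area_ratio, mean_gray)`.
#' @param ranges A [class_ranges()].
#' @return List with `counts` (named counts for bulge/protrusion/extrusion)
#'   and `per_indicator` (the five individual votes, in priority order).
#' @export
indicator_votes <- function(v, ranges = class_ranges()) {
  v <- as.numeric(v)
  stopifnot(length(v) == 5L, all(is.finite(v)))
  per <- c(distance = vote_increasing(v[1], ranges$distance),
           area = vote_increasing(v[2], ranges$area),
           length_ratio = vote_increasing(v[3], ranges$length_ratio),
           area_ratio = vote_increasing(v[4], ranges$area_ratio),
           mean_gray = vote_gray(v[5], ranges))
  counts <- vapply(c("bulge", "protrusion", "extrusion"),
                   function(g) sum(per == g), integer(1))
  list(counts = counts, per_indicator = per)
}

#' Classify an indicator vector into a herniation grade
#'
#' Decision procedure:
#' 1. if the protrusion part is absent or tiny (`area_mm2 <
#'    normal_area_mm2` *and* `distance_mm < normal_distance_mm`) the disc is
#'    `normal`;
#' 2. otherwise, a grade collecting at least 3 of the 5 indicator votes wins
#'    (at most one grade can);
#' 3. otherwise the indicators are walked in the fixed priority order
#'    (protrusion distance, protrusion area, length ratio, area ratio, mean
#'    gray) and the first indicator that votes for any grade decides;
#' 4. if no indicator votes, the disc is `normal`.
#'
#' @param v Indicator vector, see [indicator_votes()].
#' @param ranges A [class_ranges()].
#' @param normal_area_mm2,normal_distance_mm "Protrusion absent or tiny"
#'   thresholds (defaults 10 mm^2 -- the smallest pathological area in the
#'   grade table -- and 1 mm).
#' @return An `ldh_diagnosis` list: `label`, `votes`, `per_indicator`,
#'   `decided_by` (`"normal_rule"`, `"majority"` or `"priority_tiebreak"`)
#'   and `indicators` (the input vector, named).
#' @examples
#' classify_herniation(c(3, 50, 0.05, 0.05, 40))     # bulge, 5 votes
#' classify_herniation(c(12, 250, 0.25, 0.25, 10))   # extrusion, 5 votes
#' classify_herniation(c(0, 0, 0, 0, 40))            # normal
#' @export
classify_herniation <- function(v, ranges = class_ranges(),
                                normal_area_mm2 = 10, normal_distance_mm = 1) {
  v <- as.numeric(v)
  stopifnot(length(v) == 5L)
  names(v) <- c("distance_mm", "area_mm2", "length_ratio", "area_ratio", "mean_gray")
  vt <- indicator_votes(v, ranges)
  if (v[["area_mm2"]] < normal_area_mm2 && v[["distance_mm"]] < normal_distance_mm) {
    label <- "normal"; decided <- "normal_rule"
  } else if (max(vt$counts) >= 3L) {
    label <- names(vt$counts)[which.max(vt$counts)]; decided <- "majority"
  } else {
    voting <- vt$per_indicator[vt$per_indicator != "none"]
    if (length(voting) == 0L) {
      label <- "normal"; decided <- "normal_rule"
    } else {
      label <- unname(voting[1]); decided <- "priority_tiebreak"
    }
  }
  structure(list(label = label, votes = vt$counts,
                 per_indicator = vt$per_indicator,
                 decided_by = decided, indicators = v),
            class = "ldh_diagnosis")
}

#' @export
print.ldh_diagnosis <- function(x, ...) {
  cat(sprintf("<diagnosis> %s (%s; votes b/p/e = %d/%d/%d)\n", x$label,
              x$decided_by, x$votes["bulge"], x$votes["protrusion"],
              x$votes["extrusion"]))
  invisible(x)
}

#' Classify a set of discs and assemble the per-case result
#'
#' Applies [classify_herniation()] to each indicator vector, merges the
#' degeneration flags, and attaches the spinal-canal continuity flag.
#'
#' @param vectors List (or 5-column matrix) of indicator vectors, top to
#'   bottom.
#' @param degenerated Logical vector, one flag per disc.
#' @param canal_continuous Scalar flag from [find_canal()].
#' @param ranges A [class_ranges()].
#' @param normal_area_mm2,normal_distance_mm See [classify_herniation()].
#' @return List with `discs` (per-disc diagnosis + `index` + `degenerated`)
#'   and `canal`.
#' @export
batch_classify <- function(vectors, degenerated, canal_continuous,
                           ranges = class_ranges(),
                           normal_area_mm2 = 10, normal_distance_mm = 1) {
  if (is.matrix(vectors)) vectors <- asplit(vectors, 1)
  if (length(vectors) != length(degenerated))
    stop("`vectors` and `degenerated` must have the same length")
  discs <- lapply(seq_along(vectors), function(i) {
    dg <- classify_herniation(vectors[[i]], ranges, normal_area_mm2, normal_distance_mm)
    dg$index <- i
    dg$degenerated <- isTRUE(degenerated[i])
    dg
  })
  list(discs = discs, canal = list(continuous = isTRUE(canal_continuous)))
}
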