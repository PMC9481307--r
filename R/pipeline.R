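#' Run the full diagnosis pipeline on one image
#'
#' Executes preprocessing, vertebra detection, demarcation-line construction,
#' disc segmentation and screening, spinal-canal continuity testing,
#' indicator computation and grading, and assembles the diagnosis report.
#' Discs are paired with demarcation lines by vertical position (which
#' reduces to i-th disc / i-th line when all structures are found); a disc
#' whose line touches the caudal vertebra, or that has no line, is reported
#' but labelled `"ungraded"` (tail discs are excluded from grading). Stage
#' failures produce a partial report with an `errors` section instead of an
#' exception. The pipeline is deterministic.
#'
#' @param input Path to an 8-bit grayscale PNG, or a [gray_image()].
#' @param config Configuration list (see [ldh_config()]).
#' @param case_id Identifier stored in the report (defaults to the file
#'   name, or `"case"` for in-memory images).
#' @param keep_intermediates Attach masks and contours to the result (used
#'   by [run_batch()] to match detections against ground truth).
#' @return An `ldh_report` list: `case_id`, `pixel_spacing_mm`,
#'   `n_vertebrae`, `vertebrae` (corners, slope, caudal flag), `discs`
#'   (per-disc label, votes, indicators, degeneration flag), `canal`,
#'   `errors`, `provenance`.
#' @export
run_case <- function(input, config = ldh_config(), case_id = NULL,
                     keep_intermediates = FALSE) {
  if (is.character(input)) {
    if (is.null(case_id)) case_id <- sub("\\.png$", "", basename(input))
    src <- input
    img <- read_gray_png(input)
  } else {
    img <- as_gray_image(input)
    if (is.null(case_id)) case_id <- "case"
    src <- "in-memory"
  }
  spacing <- pixel_spacing(img)
  if (is.na(spacing)) spacing <- config$pixel_spacing_mm
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  pre <- tryCatch(preprocess(img, config$preprocess),
                  error = function(e) { note("preprocess", e); img })

  verts <- tryCatch(detect_vertebrae(pre, config$vertebra),
                    error = function(e) { note("vertebra", e); list() })
  lines <- tryCatch(demarcation_lines(verts),
                    error = function(e) { note("demarcation", e); list() })

  dmask <- tryCatch(segment_discs(pre, config$disc),
                    error = function(e) { note("disc", e); NULL })
  discs <- list()
  if (!is.null(dmask)) {
    vxr <- if (length(verts)) range(unlist(lapply(verts, function(v)
      range(v$contour$pixels[, 1])))) else NULL
    discs <- tryCatch(screen_disc_contours(extract_contours(dmask), config$disc, vxr),
                      error = function(e) { note("disc_screen", e); list() })
  }

  canal <- list(continuous = NA, coverage = NA_real_)
  if (!is.null(dmask) && length(verts) > 0L)
    canal <- tryCatch(find_canal(dmask, verts, config$canal)[c("continuous", "coverage")],
                      error = function(e) { note("canal", e); canal })

  # pair discs with lines by vertical position (each line used once)
  line_y <- vapply(lines, function(ln) mean(c(ln$p_top[2], ln$p_bottom[2])), numeric(1))
  disc_y <- vapply(discs, function(ct) unname(ct$centroid["y"]), numeric(1))
  assign <- rep(NA_integer_, length(discs))
  if (length(discs) && length(lines)) {
    cand <- expand.grid(d = seq_along(discs), l = seq_along(lines))
    cand$gap <- abs(disc_y[cand$d] - line_y[cand$l])
    cand <- cand[order(cand$gap), ]
    used <- logical(length(lines))
    for (k in seq_len(nrow(cand))) {
      d <- cand$d[k]; l <- cand$l[k]
      if (is.na(assign[d]) && !used[l]) { assign[d] <- l; used[l] <- TRUE }
    }
  }

  gray_img <- if (identical(config$indicators$gray_source, "raw")) img else pre
  ranges <- ranges_from_config(config)
  disc_entries <- lapply(seq_along(discs), function(i) {
    ct <- discs[[i]]
    li <- assign[i]
    mean_gray <- mean(unclass(gray_img)[cbind(ct$pixels[, 2] + 1, ct$pixels[, 1] + 1)])
    degen <- unname(degeneration_flags(mean_gray, config$indicators$degeneration_threshold))
    gradable <- !is.na(li) && !isTRUE(lines[[li]]$caudal)
    if (gradable) {
      v <- compute_indicators(ct, lines[[li]], gray_img, spacing)
      dg <- classify_herniation(v, ranges,
                                config$indicators$normal_area_mm2,
                                config$indicators$normal_distance_mm)
      list(index = i, label = dg$label, decided_by = dg$decided_by,
           votes = as.list(dg$votes), indicators = as.list(v),
           degenerated = degen, graded = TRUE)
    } else {
      list(index = i, label = "ungraded", decided_by = NA_character_,
           votes = NULL, indicators = list(mean_gray = mean_gray),
           degenerated = degen, graded = FALSE)
    }
  })

  report <- structure(list(
    case_id = case_id,
    pixel_spacing_mm = spacing,
    n_vertebrae = length(verts),
    vertebrae = lapply(verts, function(v) list(
      corners = lapply(v$corners, as.numeric),
      fit_slope = v$fit_slope, is_caudal = v$is_caudal)),
    discs = disc_entries,
    canal = canal,
    errors = errors,
    provenance = list(
      package = "ldhgrade",
      version = as.character(utils::packageVersion("ldhgrade")),
      input = src,
      input_md5 = if (src != "in-memory") unname(tools::md5sum(src)) else NA_character_,
      config_md5 = config_md5(config))), class = "ldh_report")
  if (keep_intermediates)
    attr(report, "intermediates") <- list(pre = pre, vertebrae = verts,
                                          lines = lines, discs = discs,
                                          disc_mask = dmask, line_assign = assign)
  report
}

config_md5 <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' @export
print.ldh_report <- function(x, ...) {
  cat(sprintf("<report> %s: %d vertebrae, %d discs, canal %s\n", x$case_id,
              x$n_vertebrae, length(x$discs),
              if (isTRUE(x$canal$continuous)) "continuous"
              else if (isFALSE(x$canal$continuous)) "interrupted" else "unknown"))
  for (d in x$discs)
    cat(sprintf("  disc %d: %-10s%s\n", d$index, d$label,
                if (isTRUE(d$degenerated)) " [degenerated]" else ""))
  invisible(x)
}

#' Write and read diagnosis reports as JSON
#'
#' @param report An `ldh_report`.
#' @param path Output path.
#' @return `write_report`: `path` invisibly; `read_report`: the report list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE),
            class = "ldh_report")
}

#' Structure recognition rate
#'
#' `100 * found / total`, the percentage formula used for vertebra and disc
#' recognition in batch summaries.
#'
#' @param found,total Counts.
#' @return Percentage.
#' @examples
#' recognition_rate(163, 169)
#' @export
recognition_rate <- function(found, total) {
  stopifnot(total > 0, found >= 0, found <= total)
  100 * found / total
}

#' Classification accuracy
#'
#' `100 * correct / (correct + false)`, the percentage of correct grade
#' decisions among all decisions.
#'
#' @param correct,false Counts of correct and false detections.
#' @return Percentage.
#' @examples
#' classification_accuracy(182, 18)
#' @export
classification_accuracy <- function(correct, false) {
  stopifnot(correct >= 0, false >= 0, correct + false > 0)
  100 * correct / (correct + false)
}

#' Run the pipeline over a directory of cases
#'
#' Processes every fixture subdirectory (containing `manifest.json` +
#' `image.png`, as written by [write_fixture()]) and every loose `*.png`
#' in `dir`. For fixtures, detections are matched against the ground-truth
#' masks (a structure counts as recovered when some accepted contour
#' overlaps it with IoU >= 0.5) and grades are scored on the non-caudal
#' discs. Unreadable cases are skipped with a warning.
#'
#' @param dir Directory of cases.
#' @param config Configuration list.
#' @return An `ldh_batch` list: `reports`, `summary` (one row per case),
#'   and -- when any case has ground truth -- `vertebra_recognition_rate`,
#'   `disc_recognition_rate`, `classification_accuracy` (percentages via
#'   [recognition_rate()] / [classification_accuracy()]).
#' @export
run_batch <- function(dir, config = ldh_config()) {
  subdirs <- list.dirs(dir, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "manifest.json"))]
  loose <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  rows <- list(); reports <- list()
  for (cs in c(subdirs, loose)) {
    res <- tryCatch(run_one_batch_case(cs, config),
                    error = function(e) { warning("skipping ", cs, ": ",
                                                  conditionMessage(e)); NULL })
    if (is.null(res)) next
    reports[[res$row$case]] <- res$report
    rows[[length(rows) + 1L]] <- res$row
  }
  summary <- if (length(rows)) do.call(rbind, lapply(rows, as.data.frame))
             else data.frame()
  out <- list(reports = reports, summary = summary)
  if (nrow(summary) && any(!is.na(summary$n_vert_true))) {
    tv <- sum(summary$n_vert_true, na.rm = TRUE)
    td <- sum(summary$n_disc_true, na.rm = TRUE)
    out$vertebra_recognition_rate <-
      if (tv > 0) recognition_rate(sum(summary$n_vert_found, na.rm = TRUE), tv) else NA_real_
    out$disc_recognition_rate <-
      if (td > 0) recognition_rate(sum(summary$n_disc_found, na.rm = TRUE), td) else NA_real_
    nc <- sum(summary$n_correct, na.rm = TRUE)
    nf <- sum(summary$n_false, na.rm = TRUE)
    out$classification_accuracy <-
      if (nc + nf > 0) classification_accuracy(nc, nf) else NA_real_
  }
  structure(out, class = "ldh_batch")
}

run_one_batch_case <- function(case_path, config) {
  if (dir.exists(case_path)) {
    fx <- read_fixture(case_path)
    report <- run_case(fx$image, config, case_id = basename(case_path),
                       keep_intermediates = TRUE)
    ev <- evaluate_case(report, fx)
    row <- c(list(case = basename(case_path)), ev)
  } else {
    report <- run_case(case_path, config)
    row <- list(case = report$case_id, n_vert_true = NA_integer_,
                n_vert_found = NA_integer_, n_disc_true = NA_integer_,
                n_disc_found = NA_integer_, n_correct = NA_integer_,
                n_false = NA_integer_, canal_ok = NA)
  }
  list(report = report, row = row)
}

# match detections to fixture masks and score grades
evaluate_case <- function(report, fx) {
  inter <- attr(report, "intermediates")
  H <- nrow(fx$image)
  pix_id <- function(pix) pix[, 2] + 1 + pix[, 1] * H
  iou_match <- function(mask, contours) {
    midx <- which(mask)
    for (i in seq_along(contours)) {
      cidx <- pix_id(contours[[i]]$pixels)
      iou <- length(intersect(midx, cidx)) / length(union(midx, cidx))
      if (iou >= 0.5) return(i)
    }
    NA_integer_
  }
  vcontours <- lapply(inter$vertebrae, function(v) v$contour)
  vfound <- sum(!is.na(vapply(fx$masks$vertebrae, iou_match, integer(1),
                              contours = vcontours)))
  dmatch <- vapply(fx$masks$discs, iou_match, integer(1), contours = inter$discs)
  truth <- fx$manifest$discs
  n_correct <- 0L; n_false <- 0L
  dist_err <- area_err <- numeric(0)
  for (i in seq_along(truth)) {
    if (isTRUE(truth[[i]]$caudal_adjacent)) next   # tail discs are not graded
    entry <- if (!is.na(dmatch[i])) report$discs[[dmatch[i]]] else NULL
    if (!is.null(entry) && isTRUE(entry$graded) &&
        identical(entry$label, truth[[i]]$true_class)) {
      n_correct <- n_correct + 1L
    } else n_false <- n_false + 1L
    if (!is.null(entry) && isTRUE(entry$graded) &&
        truth[[i]]$indicators$distance_mm > 0) {
      dist_err <- c(dist_err, abs(entry$indicators$distance_mm -
                                    truth[[i]]$indicators$distance_mm))
      area_err <- c(area_err, abs(entry$indicators$area_mm2 -
                                    truth[[i]]$indicators$area_mm2))
    }
  }
  canal_ok <- identical(isTRUE(report$canal$continuous),
                        !isTRUE(fx$manifest$canal$interrupted))
  list(n_vert_true = length(fx$masks$vertebrae), n_vert_found = vfound,
       n_disc_true = sum(!vapply(truth, function(d) isTRUE(d$caudal_adjacent), logical(1))),
       n_disc_found = sum(!is.na(dmatch[!vapply(truth, function(d)
         isTRUE(d$caudal_adjacent), logical(1))])),
       n_correct = n_correct, n_false = n_false, canal_ok = canal_ok,
       max_dist_err_mm = if (length(dist_err)) max(dist_err) else NA_real_,
       max_area_err_mm2 = if (length(area_err)) max(area_err) else NA_real_)
}

#' @export
print.ldh_batch <- function(x, ...) {
  cat(sprintf("<batch> %d cases\n", length(x$reports)))
  if (!is.null(x$vertebra_recognition_rate))
    cat(sprintf("  vertebra recognition %.2f%%, disc recognition %.2f%%, accuracy %.2f%%\n",
                x$vertebra_recognition_rate, x$disc_recognition_rate,
                x$classification_accuracy))
  invisible(x)
}
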