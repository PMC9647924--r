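# End-to-end pipeline: case directory in, charting outputs (assignments,
# FMS template, RBL report, evaluation) out. Each radiograph is processed
# independently; failures are logged and skipped, never aborting the batch.

#' Pipeline run configuration
#'
#' @param input_dir Case directory in the [write_case()] layout (images +
#'   masks + `case_manifest.json`). The stored masks play the role of the
#'   segmentation-model output; plug a different segmentation via the
#'   `segmentation` hook of [run_pipeline()].
#' @param output_dir Where outputs are written.
#' @param mode `"panoramic_view"` (match against the case's own panoramic)
#'   or `"repository"` (match against a saved repository).
#' @param repo_dir Repository directory (required in repository mode).
#' @param scales,k Matching parameters; see [assign_number()].
#' @param ji_threshold Successful-match Jaccard cut for evaluation
#'   (default 0.7).
#' @param clean_threshold,clean_sigma,clean_min_area [clean_mask()]
#'   parameters applied to tooth and bone masks.
#' @param seed Integer seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @param montage Also write a composite FMS montage PNG.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       mode = c("panoramic_view", "repository"),
                       repo_dir = NULL,
                       scales = seq(0.5, 1.5, by = 0.05), k = 10L,
                       ji_threshold = 0.7,
                       clean_threshold = 0.5, clean_sigma = 1,
                       clean_min_area = 50L,
                       seed = 1L, montage = TRUE) {
  mode <- match.arg(mode)
  if (mode == "repository" && is.null(repo_dir))
    stop("repository mode requires repo_dir")
  stopifnot(ji_threshold > 0, ji_threshold < 1, k >= 1)
  structure(list(input_dir = input_dir, output_dir = output_dir, mode = mode,
                 repo_dir = repo_dir, scales = scales, k = as.integer(k),
                 ji_threshold = ji_threshold,
                 clean_threshold = clean_threshold, clean_sigma = clean_sigma,
                 clean_min_area = as.integer(clean_min_area),
                 seed = as.integer(seed), montage = montage),
            class = "run_config")
}

process_intraoral_image <- function(im, config, refs) {
  tooth <- clean_mask(im$tooth_mask, config$clean_threshold,
                      config$clean_sigma, config$clean_min_area)
  bone <- clean_mask(im$bone_mask, config$clean_threshold,
                     config$clean_sigma, config$clean_min_area)
  position <- detect_position(bone, im$cej_mask)
  if (position == "bitewing") {
    cejs <- connect_cej_pair(im$cej_mask)
    boxes <- boxes_from_intraoral(tooth, cejs, "bitewing")
  } else {
    cej <- connect_cej(clean_mask(im$cej_mask, sigma = 0, min_area = 0L))
    boxes <- boxes_from_intraoral(tooth, cej, position)
  }
  crops <- crop_teeth(im$image, boxes, provenance = im$id)
  assignments <- if (config$mode == "repository")
    lapply(crops, assign_number, repo = refs$repo, scales = config$scales,
           k = config$k)
  else lapply(crops, assign_number, repo = refs$pan_repo,
              scales = config$scales, k = config$k, mode = "panoramic_view")
  rbl <- NULL
  if (position != "bitewing" && nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      for (ed in c("left", "right")) {
        lm <- tryCatch(
          landmarks_from_masks(boxes[i, ], cej, bone,
                               side = if (ed == "left") "mesial" else "distal",
                               edge = ed, provenance = im$id),
          error = function(e) NULL)
        if (!is.null(lm))
          rbl <- rbind(rbl, cbind(image = im$id,
                                  tooth_report(assignments[[i]], lm)))
      }
    }
  }
  list(id = im$id, position = position, boxes = boxes,
       assignments = assignments, rbl = rbl)
}

#' Run the charting pipeline on a case directory
#'
#' Reads a case, cleans the masks, detects positions, extracts and numbers
#' every tooth, measures RBL on periapicals, arranges the set into the FMS
#' template, and (when gold annotations are present) evaluates detection,
#' numbering and position against them. Per-image failures are logged in
#' `log.txt` and the image is skipped.
#'
#' @param config A [run_config()].
#' @param segmentation Optional hook `function(image, kind)` returning
#'   `list(tooth =, bone =, cej =)` raw masks; by default the masks stored
#'   with the case are used.
#' @return The output directory, invisibly; outputs are
#'   `assignments.json`, `fms_template.json`, `rbl_report.csv`,
#'   `evaluation.json` (if gold present), `log.txt` and optionally
#'   `fms_montage.png`.
#' @export
run_pipeline <- function(config, segmentation = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "log.txt")
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (!file.exists(file.path(config$input_dir, "case_manifest.json"))) {
    note("empty input: no case_manifest.json in %s", config$input_dir)
    writeLines(log_lines, logf)
    warning("empty input directory; empty outputs written")
    jsonlite::write_json(list(), file.path(config$output_dir, "assignments.json"))
    return(invisible(config$output_dir))
  }
  case <- read_case(config$input_dir)
  imgs <- c(case$periapicals, case$bitewings)
  refs <- list()
  if (config$mode == "repository") {
    refs$repo <- load_repository(config$repo_dir)
    if (length(refs$repo$entries) == 0L) stop("empty repository")
  } else {
    pan_mask <- clean_mask(case$panoramic$tooth_mask, config$clean_threshold,
                           config$clean_sigma, config$clean_min_area)
    boxes <- label_panoramic_boxes(boxes_from_panoramic(pan_mask))
    boxes <- boxes[!is.na(boxes$fdi), ]
    crops <- crop_teeth(case$panoramic$image, boxes)
    refs$pan_repo <- new_repository(lapply(seq_along(crops), function(i)
      list(crop = crops[[i]]$patch, fdi = boxes$fdi[i],
           source_id = "panoramic")))
    note("panoramic-view mode: %d transient repository entries", nrow(boxes))
  }
  results <- list()
  for (im in imgs) {
    r <- tryCatch(process_intraoral_image(im, config, refs),
                  error = function(e) {
                    note("FAILED %s: %s", im$id, conditionMessage(e))
                    NULL
                  })
    if (!is.null(r)) {
      results[[r$id]] <- r
      note("ok %s: position=%s, %d teeth", r$id, r$position, nrow(r$boxes))
    }
  }
  # assignments
  asn <- lapply(results, function(r) {
    lapply(seq_along(r$assignments), function(i) {
      a <- r$assignments[[i]]
      list(image = r$id, box = as.list(r$boxes[i, c("x0", "y0", "x1", "y1")]),
           fdi = a$fdi, mode = a$mode, votes = as.list(a$votes))
    })
  })
  jsonlite::write_json(asn, file.path(config$output_dir, "assignments.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # FMS template
  fms <- arrange_fms(lapply(results, function(r)
    list(id = r$id, position = r$position, assignments = r$assignments)))
  jsonlite::write_json(
    list(top = fms$top, middle = fms$middle, bottom = fms$bottom,
         unplaced = fms$unplaced),
    file.path(config$output_dir, "fms_template.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # RBL report
  rbl <- do.call(rbind, lapply(results, `[[`, "rbl"))
  if (is.null(rbl)) rbl <- data.frame(image = character(0), fdi = integer(0),
                                      side = character(0),
                                      rbl_percent = numeric(0),
                                      stage = integer(0))
  write.csv(rbl, file.path(config$output_dir, "rbl_report.csv"),
            row.names = FALSE)
  # evaluation against gold, when present
  has_gold <- any(vapply(imgs, function(im) !is.null(im$teeth), TRUE))
  if (has_gold && length(results)) {
    evals <- list(); truth <- integer(0); pred <- integer(0)
    pos_truth <- character(0); pos_pred <- character(0)
    for (im in imgs) {
      r <- results[[im$id]]
      if (is.null(r) || is.null(im$teeth)) next
      pb <- r$boxes
      pb$fdi <- vapply(r$assignments, `[[`, 0L, "fdi")
      ev <- evaluate_detection(pb, im$teeth, config$ji_threshold)
      evals[[im$id]] <- ev[c("n_detected", "n_gold", "n_successful",
                             "n_true_number", "detection_precision",
                             "detection_recall", "numbering_precision",
                             "numbering_recall")]
      if (NROW(ev$pairs)) {
        truth <- c(truth, im$teeth$fdi[ev$pairs$g])
        pred <- c(pred, pb$fdi[ev$pairs$p])
      }
      pos_truth <- c(pos_truth, im$position)
      pos_pred <- c(pos_pred, r$position)
    }
    summary <- list(
      per_image = evals,
      numbering_accuracy = if (length(truth)) numbering_accuracy(truth, pred)
                           else NA,
      position_accuracy = if (length(pos_truth))
        position_accuracy(pos_truth, pos_pred) else NA)
    jsonlite::write_json(summary,
                         file.path(config$output_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (isTRUE(config$montage)) {
    tryCatch(write_fms_montage(fms, imgs,
                               file.path(config$output_dir, "fms_montage.png")),
             error = function(e) note("montage failed: %s",
                                      conditionMessage(e)))
  }
  writeLines(log_lines, logf)
  invisible(config$output_dir)
}

# Composite 3-row montage of the arranged FMS for visual review.
write_fms_montage <- function(fms, imgs, path, thumb = 96L) {
  by_id <- setNames(imgs, vapply(imgs, `[[`, "", "id"))
  rows <- list(fms$top, fms$middle, fms$bottom)
  ncols <- max(1L, max(vapply(rows, length, 0L)))
  canvas <- matrix(0, 3L * thumb, ncols * thumb)
  for (ri in seq_along(rows)) {
    for (ci in seq_along(rows[[ri]])) {
      im <- by_id[[rows[[ri]][[ci]]$id]]
      if (is.null(im)) next
      th <- resize_gray(im$image, thumb, thumb)
      canvas[((ri - 1) * thumb + 1):(ri * thumb),
             ((ci - 1) * thumb + 1):(ci * thumb)] <- th
    }
  }
  png::writePNG(clamp(canvas, 0, 1), path)
  invisible(path)
}
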