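# FDI assignment by multi-scale template matching. Similarity is
# zero-normalized cross-correlation (ZNCC) of the histogram-equalized crop,
# resized over a scale grid and slid over each repository entry; the top-k
# scores vote on the tooth number.

#' Histogram-equalize a grayscale patch
#'
#' Rank-based equalization to `[0, 1]`; damps exposure and contrast
#' differences between intraoral crops and panoramic repository entries
#' before correlation. Monotone, hence order-preserving.
#'
#' @param m Numeric matrix.
#' @return Equalized matrix.
#' @export
equalize_hist <- function(m) {
  v <- as.vector(m)
  if (length(unique(v)) <= 1L) return(m)
  matrix(ecdf(v)(v), nrow(m), ncol(m))
}

# Pad `img` centrally (with its mean) so that `tmpl` fits; dimensions where
# it already fits are untouched.
pad_to_fit <- function(img, th, tw) {
  ih <- nrow(img); iw <- ncol(img)
  if (th <= ih && tw <= iw) return(img)
  oh <- max(ih, th); ow <- max(iw, tw)
  out <- matrix(mean(img), oh, ow)
  r0 <- (oh - ih) %/% 2L; c0 <- (ow - iw) %/% 2L
  out[(r0 + 1):(r0 + ih), (c0 + 1):(c0 + iw)] <- img
  out
}

# ZNCC of an already-equalized template against an already-equalized entry.
score_pair <- function(tmpl, entry) {
  entry <- pad_to_fit(entry, nrow(tmpl), ncol(tmpl))
  s <- cpp_zncc_best(tmpl, entry)
  if (is.na(s)) {
    warning("degenerate (constant) patch; score defined as 0")
    s <- 0
  }
  s
}

as_patch <- function(x) {
  if (inherits(x, "tooth_crop")) x$patch
  else if (is.list(x) && !is.null(x$crop)) x$crop
  else if (is.matrix(x)) x
  else stop("expected a tooth_crop, repository entry, or matrix")
}

#' Score one crop against one repository entry at one scale
#'
#' The crop is resized by `scale`, both patches are histogram-equalized, and
#' the crop is slid over the entry (the entry is mean-padded where the
#' resized crop is larger); the score is the maximum zero-normalized
#' cross-correlation, in `[-1, 1]`.
#'
#' @param crop A `tooth_crop` or matrix.
#' @param entry A repository entry (list with `$crop`) or matrix.
#' @param scale Positive resize factor applied to the crop.
#' @param entry_ref Optional repository index recorded in the result.
#' @return List of class `match_score` with `score`, `scale`, `entry_ref`.
#' @export
match_score <- function(crop, entry, scale = 1, entry_ref = NA_integer_) {
  stopifnot(scale > 0)
  cp <- as_patch(crop); ep <- as_patch(entry)
  if (length(cp) == 0L || length(ep) == 0L) stop("empty patch")
  tmpl <- equalize_hist(resize_gray(cp, nrow(cp) * scale, ncol(cp) * scale))
  structure(list(score = score_pair(tmpl, equalize_hist(ep)),
                 scale = scale, entry_ref = entry_ref),
            class = "match_score")
}

#' Assign an FDI number to a tooth crop by top-k majority voting
#'
#' Every repository entry is scored at its best scale over `scales`; entries
#' are ranked by score, the top `k` vote with their FDI labels, and the
#' majority wins. Vote ties are broken by the larger mean score among tied
#' labels, then by the single best score, then by the smaller FDI number.
#'
#' @param crop A `tooth_crop` or matrix.
#' @param repo A `tooth_repository` (non-empty).
#' @param scales Scale grid (default 0.5 to 1.5 in steps of 0.05).
#' @param k Number of top scores that vote (default 10).
#' @param mode Recorded provenance of the reference: `"repository"` or
#'   `"panoramic_view"`.
#' @return List of class `fdi_assignment`: `fdi`, `votes` (named counts over
#'   the top k), `top_scores` (data frame, descending score), `mode`,
#'   `provenance`.
#' @export
assign_number <- function(crop, repo, scales = seq(0.5, 1.5, by = 0.05),
                          k = 10L, mode = "repository") {
  stopifnot(inherits(repo, "tooth_repository"), k >= 1L, length(scales) >= 1L)
  if (length(repo$entries) == 0L) stop("empty repository")
  cp <- as_patch(crop)
  tmpls <- lapply(scales, function(s)
    equalize_hist(resize_gray(cp, nrow(cp) * s, ncol(cp) * s)))
  best <- do.call(rbind, lapply(seq_along(repo$entries), function(i) {
    ep <- equalize_hist(repo$entries[[i]]$crop)
    sc <- vapply(tmpls, function(t) suppressWarnings(score_pair(t, ep)), 0)
    j <- which.max(sc)
    data.frame(entry_ref = i, fdi = repo$entries[[i]]$fdi,
               scale = scales[j], score = sc[j])
  }))
  best <- best[order(-best$score, best$entry_ref), ]
  top <- utils::head(best, k)
  votes <- sort(table(top$fdi), decreasing = TRUE)
  vmax <- votes[votes == max(votes)]
  tied <- as.integer(names(vmax))
  if (length(tied) > 1L) {
    meansc <- vapply(tied, function(f) mean(top$score[top$fdi == f]), 0)
    maxsc <- vapply(tied, function(f) max(top$score[top$fdi == f]), 0)
    tied <- tied[order(-meansc, -maxsc, tied)]
  }
  structure(list(fdi = tied[1],
                 votes = setNames(as.integer(votes), names(votes)),
                 top_scores = top, mode = mode,
                 provenance = if (inherits(crop, "tooth_crop"))
                   crop$provenance else NA_character_),
            class = "fdi_assignment")
}

#' @export
print.fdi_assignment <- function(x, ...) {
  cat(sprintf("fdi_assignment: %d (%s mode, %d/%d votes, best score %.3f)\n",
              x$fdi, x$mode, x$votes[as.character(x$fdi)],
              sum(x$votes), max(x$top_scores$score)))
  invisible(x)
}

# Label panoramic boxes by arch order: split the two rows of boxes at the
# largest vertical gap between box centers, then walk each row left to right
# along the FDI sequence (18..11, 21..28 above; 48..41, 31..38 below),
# skipping slots across gaps wider than gap_mult x the median inter-box gap.
label_panoramic_boxes <- function(boxes, gap_mult = 1.5) {
  if (nrow(boxes) == 0L) stop("panoramic with zero extracted teeth")
  cy <- (boxes$y0 + boxes$y1) / 2
  ord <- order(cy)
  gaps <- diff(cy[ord])
  if (length(gaps) == 0L || max(gaps) < 0.1 * max(boxes$y1))
    stop("cannot separate maxillary and mandibular rows of panoramic boxes")
  cut <- cy[ord][which.max(gaps)]
  boxes$arch <- ifelse(cy <= cut, "maxilla", "mandible")
  boxes$fdi <- NA_integer_
  for (arch in c("maxilla", "mandible")) {
    seq_fdi <- if (arch == "maxilla") c(18:11, 21:28) else c(48:41, 31:38)
    idx <- which(boxes$arch == arch)
    idx <- idx[order(boxes$x0[idx])]
    if (length(idx) == 0L) next
    w <- boxes$x1[idx] - boxes$x0[idx]
    g <- if (length(idx) > 1L) boxes$x0[idx][-1] - boxes$x1[idx][-length(idx)]
         else numeric(0)
    med_g <- if (length(g)) median(g) else 0
    med_w <- median(w)
    slot <- 1L
    for (j in seq_along(idx)) {
      if (j > 1L && g[j - 1L] > gap_mult * med_g)
        slot <- slot + max(1L, as.integer(round((g[j - 1L] - med_g) /
                                                  (med_w + med_g))))
      if (slot > length(seq_fdi)) {
        warning("more panoramic teeth than arch slots; extra boxes unlabeled")
        break
      }
      boxes$fdi[idx[j]] <- seq_fdi[slot]
      slot <- slot + 1L
    }
  }
  boxes
}

#' Assign FDI numbers by matching against the patient's own panoramic
#'
#' Builds a transient repository from the panoramic's extracted teeth,
#' labeled purely by arch order (left to right mapped onto the FDI sequence,
#' with gaps wider than `gap_mult` times the median inter-box gap treated as
#' missing teeth), then delegates to [assign_number()].
#'
#' @param crops List of `tooth_crop`s from intraoral radiographs.
#' @param panoramic_image Grayscale panoramic matrix.
#' @param panoramic_tooth_mask Cleaned binary tooth mask of the panoramic.
#' @param scales,k Passed to [assign_number()].
#' @param gap_mult Missing-tooth gap threshold multiplier (default 1.5).
#' @return List of `fdi_assignment`s, `mode = "panoramic_view"`; the labeled
#'   panoramic boxes are attached as `attr(, "panoramic_boxes")`.
#' @export
assign_numbers_via_panoramic <- function(crops, panoramic_image,
                                         panoramic_tooth_mask,
                                         scales = seq(0.5, 1.5, by = 0.05),
                                         k = 10L, gap_mult = 1.5) {
  boxes <- boxes_from_panoramic(panoramic_tooth_mask)
  boxes <- label_panoramic_boxes(boxes, gap_mult)
  keep <- !is.na(boxes$fdi)
  boxes <- boxes[keep, ]
  pan_crops <- crop_teeth(panoramic_image, boxes, provenance = "panoramic")
  repo <- new_repository(lapply(seq_along(pan_crops), function(i)
    list(crop = pan_crops[[i]]$patch, fdi = boxes$fdi[i],
         source_id = "panoramic")))
  out <- lapply(crops, assign_number, repo = repo, scales = scales, k = k,
                mode = "panoramic_view")
  attr(out, "panoramic_boxes") <- boxes
  out
}
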