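# Radiographic bone loss (RBL) and periodontal staging under the 2018
# classification: RBL = 100 x (CEJ -> alveolar crest) / (CEJ -> root apex),
# measured along the CEJ-apex axis; Stage 1 < 15%, Stage 2 15-33%,
# Stage 3 > 33%.

#' Per-tooth periodontal landmarks
#'
#' @param cej_point,bone_point,apex_point Numeric `(x, y)` pairs: the CEJ
#'   reference, the alveolar bone crest, and the root apex. The bone point
#'   must project onto the CEJ-apex segment (projection parameter in
#'   `[0, 1]`, small tolerance for raster quantization).
#' @param side `"mesial"` or `"distal"`.
#' @param provenance Optional crop/image identifier.
#' @return List of class `tooth_landmarks`.
#' @export
tooth_landmarks <- function(cej_point, bone_point, apex_point,
                            side = c("mesial", "distal"),
                            provenance = NA_character_) {
  side <- match.arg(side)
  pts <- list(cej = cej_point, bone = bone_point, apex = apex_point)
  stopifnot(all(lengths(pts) == 2L))
  if (isTRUE(all.equal(cej_point, apex_point)))
    stop("zero root length: CEJ and apex coincide")
  if (identical(cej_point, bone_point) && identical(bone_point, apex_point))
    stop("landmarks must be pairwise distinct")
  ax <- apex_point - cej_point
  t <- sum((bone_point - cej_point) * ax) / sum(ax * ax)
  if (t < -0.05 || t > 1.05)
    stop("bone point does not lie between CEJ and apex (projection ", round(t, 3), ")")
  structure(list(cej_point = as.numeric(cej_point),
                 bone_point = as.numeric(bone_point),
                 apex_point = as.numeric(apex_point),
                 side = side, provenance = provenance),
            class = "tooth_landmarks")
}

#' Radiographic bone loss percentage
#'
#' `100 x` the CEJ-to-crest distance (projected on the CEJ-apex axis) over
#' the CEJ-to-apex distance, clipped to `[0, 100]`.
#'
#' @param landmarks A [tooth_landmarks()].
#' @return RBL percentage in `[0, 100]`.
#' @export
compute_rbl <- function(landmarks) {
  stopifnot(inherits(landmarks, "tooth_landmarks"))
  ax <- landmarks$apex_point - landmarks$cej_point
  len <- sqrt(sum(ax * ax))
  if (len == 0) stop("zero root length: CEJ and apex coincide")
  proj <- sum((landmarks$bone_point - landmarks$cej_point) * ax) / len
  clamp(100 * proj / len, 0, 100)
}

#' Periodontal stage from an RBL percentage
#'
#' 2018 classification thresholds: Stage 1 for RBL < 15% (coronal third of
#' the root), Stage 2 for 15% <= RBL <= 33%, Stage 3 for RBL > 33%
#' (middle third and beyond).
#'
#' @param rbl_percent Value(s) in `[0, 100]`.
#' @return Integer stage(s) in `{1, 2, 3}`.
#' @export
assign_stage <- function(rbl_percent) {
  if (any(is.na(rbl_percent)) || any(rbl_percent < 0) || any(rbl_percent > 100))
    stop("RBL percentage must be in [0, 100]")
  ifelse(rbl_percent < 15, 1L, ifelse(rbl_percent <= 33, 2L, 3L))
}

#' Per-tooth diagnostic record
#'
#' Combines an FDI assignment with measured landmarks into one record per
#' annotated side; both inputs must refer to the same crop.
#'
#' @param assignment An `fdi_assignment`.
#' @param landmarks A `tooth_landmarks`.
#' @return One-row data frame: `fdi`, `side`, `rbl_percent`, `stage`.
#' @export
tooth_report <- function(assignment, landmarks) {
  stopifnot(inherits(assignment, "fdi_assignment"),
            inherits(landmarks, "tooth_landmarks"))
  pa <- assignment$provenance; pl <- landmarks$provenance
  if (!is.na(pa) && !is.na(pl) && !identical(pa, pl))
    stop("assignment and landmarks refer to different crops: ",
         pa, " vs ", pl)
  rbl <- compute_rbl(landmarks)
  data.frame(fdi = assignment$fdi, side = landmarks$side,
             rbl_percent = rbl, stage = assign_stage(rbl))
}

#' Extract periodontal landmarks from masks
#'
#' Rule-based localization for one tooth box: the CEJ point is the polyline
#' at the mesial/distal box edge, the apex is the rootward extreme of the
#' tooth component, and the bone point is the first bone-mask pixel met when
#' walking the CEJ-to-apex segment (sampled at quarter-pixel steps). When no
#' bone pixel is met the crest is taken at the CEJ (zero loss).
#'
#' @param box One-row box data frame from [boxes_from_intraoral()] (needs
#'   `apex_x`, `apex_y`).
#' @param cej CEJ polyline.
#' @param bone_mask Cleaned binary bone mask.
#' @param side `"mesial"` or `"distal"`: which vertical box edge carries the
#'   CEJ point. For patient-right quadrants the mesial side is the
#'   higher-x edge; callers that do not track quadrants can treat the two
#'   edges as the two sides.
#' @param edge `"left"` or `"right"` box edge used for the CEJ point.
#' @param provenance Optional crop identifier.
#' @return A [tooth_landmarks()].
#' @export
landmarks_from_masks <- function(box, cej, bone_mask, side = "mesial",
                                 edge = c("left", "right"),
                                 provenance = NA_character_) {
  edge <- match.arg(edge)
  x_edge <- if (edge == "left") box$x0 else box$x1 - 1L
  x_edge <- clamp(x_edge, min(cej$x), max(cej$x))
  cej_pt <- c(x_edge, polyline_y_at(cej, x_edge))
  apex_pt <- c(box$apex_x, box$apex_y)
  seg <- apex_pt - cej_pt
  len <- sqrt(sum(seg * seg))
  bone_pt <- cej_pt
  for (t in seq(0, 1, by = 0.25 / max(1, len))) {
    p <- round(cej_pt + t * seg)
    if (p[1] >= 0 && p[2] >= 0 && p[1] < ncol(bone_mask) &&
        p[2] < nrow(bone_mask) && bone_mask[p[2] + 1L, p[1] + 1L] != 0L) {
      bone_pt <- cej_pt + t * seg
      break
    }
  }
  tooth_landmarks(cej_pt, bone_pt, apex_pt, side = side,
                  provenance = provenance)
}
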