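# Per-tooth bounding boxes and crops. Panoramic boxes are contour extents;
# intraoral boxes follow the four-point rule: mesial and distal tooth-CEJ
# intersection points plus the root apex (apexes for bitewings).

#' Tooth bounding boxes from a panoramic tooth mask
#'
#' One axis-aligned box per 8-connected component (the component's contour
#' extent), ordered left to right. Two teeth merged into one component yield
#' a single box; components are never split.
#'
#' @param tooth_mask Cleaned binary tooth mask.
#' @return Data frame of half-open boxes `x0, y0, x1, y1` (0-based) with a
#'   `component` column, ordered by `x0`.
#' @export
boxes_from_panoramic <- function(tooth_mask) {
  stopifnot(is.matrix(tooth_mask))
  bin <- as_binary(tooth_mask)
  if (!any(bin != 0L)) return(empty_boxes())
  lab <- cpp_label8(bin)
  n <- max(lab)
  boxes <- do.call(rbind, lapply(seq_len(n), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    new_box(min(px[, 2]) - 1L, min(px[, 1]) - 1L,
            max(px[, 2]), max(px[, 1]), component = i)
  }))
  boxes <- boxes[order(boxes$x0), ]
  rownames(boxes) <- NULL
  boxes$source_kind <- "panoramic"
  boxes
}

#' Tooth bounding boxes from an intraoral tooth mask and CEJ polyline
#'
#' For every tooth component the mesial and distal CEJ crossings (the
#' extreme-x contour points lying within `tol` rows of the polyline) and the
#' root apex (the rootward extreme: minimum y for maxilla, maximum y for
#' mandible, both per half for bitewings) define a four-point box, padded by
#' `pad` pixels and clipped to the raster. Components that never cross the
#' CEJ are skipped with a warning and count as missed detections.
#'
#' @param tooth_mask Cleaned binary tooth mask.
#' @param cej A polyline from [connect_cej()]; for `position = "bitewing"` a
#'   list of two polylines (`upper`, `lower`) from [connect_cej_pair()], or a
#'   raw CEJ mask from which the pair is derived.
#' @param position `"maxilla"`, `"mandible"` or `"bitewing"`.
#' @param tol CEJ-crossing tolerance in rows (default 3).
#' @param pad Box padding in pixels (default 2).
#' @return Data frame of half-open boxes ordered by `x0`, with `component`
#'   and `arch` columns.
#' @export
boxes_from_intraoral <- function(tooth_mask, cej,
                                 position = c("maxilla", "mandible", "bitewing"),
                                 tol = 3L, pad = 2L) {
  position <- match.arg(position)
  stopifnot(is.matrix(tooth_mask))
  bin <- as_binary(tooth_mask)
  if (!any(bin != 0L)) return(empty_boxes())
  if (position == "bitewing") {
    if (is.matrix(cej)) cej <- connect_cej_pair(cej)
    stopifnot(is.list(cej), !is.null(cej$upper), !is.null(cej$lower))
    mid <- mean(c(mean(cej$upper$y), mean(cej$lower$y)))
  } else {
    stopifnot(is.data.frame(cej))
  }
  lab <- cpp_label8(bin)
  dims <- dim(bin)
  out <- NULL
  skipped <- 0L
  for (i in seq_len(max(lab))) {
    px <- which(lab == i, arr.ind = TRUE)
    xs <- px[, 2] - 1L; ys <- px[, 1] - 1L
    if (position == "bitewing") {
      upper_half <- mean(ys) < mid
      poly <- if (upper_half) cej$upper else cej$lower
      arch <- if (upper_half) "maxilla" else "mandible"
    } else {
      poly <- cej
      arch <- position
    }
    py <- polyline_y_at(poly, xs)
    near <- abs(ys - py) <= tol
    if (!any(near)) { skipped <- skipped + 1L; next }
    xl <- min(xs[near]); xr <- max(xs[near])
    cej_pts_y <- c(polyline_y_at(poly, xl), polyline_y_at(poly, xr))
    apex_y <- if (arch == "maxilla") min(ys) else max(ys)
    apex_x <- if (arch == "maxilla") xs[which.min(ys)] else xs[which.max(ys)]
    pts_x <- c(xl, xr, apex_x); pts_y <- c(cej_pts_y, apex_y)
    b <- new_box(max(0L, min(pts_x) - pad), max(0L, min(pts_y) - pad),
                 min(dims[2], max(pts_x) + 1L + pad),
                 min(dims[1], max(pts_y) + 1L + pad),
                 component = i, arch = arch,
                 apex_x = apex_x, apex_y = apex_y)
    out <- rbind(out, b)
  }
  if (skipped > 0L)
    warning(sprintf("%d tooth component(s) had no CEJ crossing within %d rows; skipped",
                    skipped, tol))
  if (is.null(out)) return(empty_boxes())
  out <- out[order(out$x0), ]
  rownames(out) <- NULL
  out$source_kind <- if (position == "bitewing") "bitewing" else "periapical"
  out
}

#' Crop teeth from an image
#'
#' Pixel-exact crops for a set of boxes, order preserved.
#'
#' @param image Numeric matrix.
#' @param boxes Data frame of half-open boxes.
#' @param provenance Optional source-image identifier stored on each crop.
#' @return List of `tooth_crop` objects (`patch`, `box`, `provenance`).
#' @export
crop_teeth <- function(image, boxes, provenance = NA_character_) {
  stopifnot(is.matrix(image))
  bad <- which(boxes$x0 < 0 | boxes$y0 < 0 |
                 boxes$x1 > ncol(image) | boxes$y1 > nrow(image) |
                 boxes$x0 >= boxes$x1 | boxes$y0 >= boxes$y1)
  if (length(bad)) stop("out-of-bounds box at index ", bad[1])
  lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    structure(list(patch = image[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1, drop = FALSE],
                   box = b, provenance = provenance),
              class = "tooth_crop")
  })
}
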