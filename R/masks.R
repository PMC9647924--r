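#' Resize and optionally heatmap-encode a radiograph
#'
#' Standardizes a grayscale radiograph to the working resolution and, when
#' requested, maps intensities through a fixed perceptual colormap to a
#' 3-channel image. Heatmap encoding gives downstream models stronger visual
#' cues than raw gray levels; the mapping is monotone in intensity so no
#' ordering information is lost.
#'
#' @param image Numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @param target_size Integer vector `c(height, width)`; default `c(512, 512)`.
#' @param heatmap If `TRUE`, return an `height x width x 3` array obtained by
#'   looking intensities up in `colormap`.
#' @param colormap Name of a [grDevices::hcl.colors()] palette; the default
#'   "viridis" is perceptually uniform and luminance-monotone.
#' @return A matrix (grayscale) or 3-d array (heatmap) of the target size.
#' @export
preprocess_image <- function(image, target_size = c(512L, 512L),
                             heatmap = FALSE, colormap = "viridis") {
  stopifnot(is.matrix(image))
  if (any(dim(image) == 0L)) stop("image has a zero dimension")
  out <- resize_gray(image, target_size[1], target_size[2])
  if (!heatmap) return(out)
  pal <- grDevices::hcl.colors(256L, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- pmin(255L, pmax(0L, as.integer(floor(out * 255)))) + 1L
  arr <- array(0, c(dim(out), 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, idx], nrow(out), ncol(out))
  arr
}

#' Clean a raw segmentation mask
#'
#' Postprocessing applied to model-produced (or synthetic) masks: Gaussian
#' filtering to suppress speckle, binarization, and removal of small connected
#' components. The output is strictly binary.
#'
#' @param raw Numeric matrix with values in `[0, 1]` (probabilities or binary).
#' @param threshold Binarization cut applied after smoothing (default 0.5).
#' @param sigma Gaussian blur standard deviation in pixels; 0 disables
#'   smoothing. Default 1. The blur targets soft (probability) rasters; a
#'   strictly binary input skips it, which makes the operator exactly
#'   idempotent and leaves already-clean masks untouched.
#' @param min_area Connected components (8-connected) smaller than this pixel
#'   count are dropped. Default 50, tuned for 512x512 rasters; scale it with
#'   image area when working at other resolutions.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
clean_mask <- function(raw, threshold = 0.5, sigma = 1, min_area = 50L) {
  stopifnot(is.matrix(raw), min(raw) >= 0, max(raw) <= 1)
  m <- raw
  if (sigma > 0 && any(m != 0 & m != 1)) m <- EBImage::gblur(m, sigma = sigma)
  bin <- as_binary(m > threshold)
  if (min_area > 0 && any(bin != 0L)) {
    lab <- cpp_label8(bin)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_area)
    if (length(drop)) bin[lab %in% drop] <- 0L
  }
  bin
}

#' Trace outer contours of a binary mask
#'
#' One closed outer contour per 8-connected component, ordered by component
#' area descending. Holes are ignored.
#'
#' @param mask Binary matrix.
#' @return List of `k x 2` integer matrices with columns `x`, `y` (0-based
#'   pixel coordinates along the boundary).
#' @export
extract_contours <- function(mask) {
  stopifnot(is.matrix(mask))
  bin <- as_binary(mask)
  if (!any(bin != 0L)) return(list())
  lab <- cpp_label8(bin)
  sizes <- tabulate(lab[lab > 0L])
  ord <- order(sizes, decreasing = TRUE)
  lapply(ord, function(i) {
    ct <- cpp_trace_boundary(lab, i)
    colnames(ct) <- c("x", "y")
    ct
  })
}

#' Connect a fragmented CEJ mask into a single polyline
#'
#' The cementoenamel-junction (CEJ) mask produced by segmentation is typically
#' fragmented per tooth. A window slides across image columns; within each
#' window the centroid of mask pixels becomes a knot, empty windows spanning at
#' most `gap_factor` windows are bridged linearly, and the knots are
#' interpolated to one point per column. The CEJ is assumed close to
#' horizontal (|slope| <= 1), which keeps consecutive points 8-connected.
#'
#' @param raw_cej Binary matrix of CEJ pixels (typically the output of
#'   [clean_mask()] with `min_area = 0`).
#' @param window Sliding-window width in columns (default 8).
#' @param gap_factor Bridge empty gaps up to `gap_factor * window` columns;
#'   longer gaps split the line and the longest segment is kept with a
#'   warning. Default 3.
#' @return Data frame with integer columns `x`, `y`: one point per column,
#'   `x` strictly increasing.
#' @export
connect_cej <- function(raw_cej, window = 8L, gap_factor = 3L) {
  stopifnot(is.matrix(raw_cej))
  px <- mask_xy(raw_cej)
  if (nrow(px) == 0L) stop("no CEJ pixels")
  x0 <- min(px$x); x1 <- max(px$x)
  breaks <- seq(x0, x1 + window, by = window)
  bin <- findInterval(px$x, breaks, rightmost.closed = FALSE)
  knots <- aggregate(px[c("x", "y")], list(bin = bin), mean)
  knots <- knots[order(knots$x), ]
  # endpoint knots so the polyline spans the full pixel column range
  ends <- data.frame(
    bin = NA,
    x = c(x0, x1),
    y = c(mean(px$y[px$x == x0]), mean(px$y[px$x == x1])))
  knots <- rbind(ends[1, ], knots, ends[2, ])
  knots <- knots[!duplicated(knots$x), ]
  # split where consecutive knots are further apart than the bridgeable gap
  gap_px <- gap_factor * window
  dx <- diff(knots$x)
  seg_id <- cumsum(c(0, dx > gap_px))
  if (max(seg_id) > 0) {
    spans <- tapply(knots$x, seg_id, function(x) diff(range(x)))
    keep <- as.integer(names(spans))[which.max(spans)]
    warning(sprintf("CEJ mask split by a gap > %d px; keeping longest of %d segments",
                    gap_px, max(seg_id) + 1L))
    knots <- knots[seg_id == keep, ]
  }
  xs <- seq(min(knots$x), max(knots$x))
  ys <- if (nrow(knots) == 1L) rep(knots$y, length(xs))
        else approx(knots$x, knots$y, xout = xs)$y
  data.frame(x = as.integer(round(xs)), y = as.integer(round(ys)))
}

#' Connect a bitewing's double CEJ mask into two polylines
#'
#' Bitewings show both arches, hence two CEJ lines. The mask is split into
#' an upper (maxillary) and lower (mandibular) branch at the widest row gap
#' and each branch is connected with [connect_cej()].
#'
#' @inheritParams connect_cej
#' @return List with polylines `upper` and `lower`.
#' @export
connect_cej_pair <- function(raw_cej, window = 8L, gap_factor = 3L) {
  px <- mask_xy(raw_cej)
  if (nrow(px) == 0L) stop("no CEJ pixels")
  rows <- sort(unique(px$y))
  if (length(rows) < 2L) stop("bitewing CEJ mask has a single branch")
  gaps <- diff(rows)
  cut <- rows[which.max(gaps)]
  upper <- lower <- matrix(0L, nrow(raw_cej), ncol(raw_cej))
  sel <- px$y <= cut
  upper[cbind(px$y[sel] + 1L, px$x[sel] + 1L)] <- 1L
  lower[cbind(px$y[!sel] + 1L, px$x[!sel] + 1L)] <- 1L
  list(upper = connect_cej(upper, window, gap_factor),
       lower = connect_cej(lower, window, gap_factor))
}

# y of a per-column polyline at given x (nearest column, clamped to its span).
polyline_y_at <- function(poly, x) {
  xi <- clamp(round(x), min(poly$x), max(poly$x))
  poly$y[match(xi, poly$x)]
}
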