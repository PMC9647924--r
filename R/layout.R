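# Radiograph position from bone/CEJ geometry, and full-mouth-series
# arrangement into the 3-row template (maxillary / bitewing / mandibular).

#' Determine an intraoral radiograph's position
#'
#' Rules, applied in order: (a) two large bone components, vertically
#' separated, mean bitewing; otherwise (b) bone centroid above the CEJ line
#' means maxilla, (c) below means mandible.
#'
#' @param bone_mask Cleaned binary bone-area mask.
#' @param cej CEJ polyline (from [connect_cej()]) or raw CEJ mask; needed
#'   only for the single-arch decision.
#' @param min_area Minimum component size (px) for a bone area to count
#'   (default 200 at 512 x 512).
#' @param sep_frac Minimum vertical centroid separation between two bone
#'   areas, as a fraction of image height, to call a bitewing (default 0.2;
#'   keeps a split bone band from masquerading as two arches).
#' @return `"maxilla"`, `"mandible"` or `"bitewing"`.
#' @export
detect_position <- function(bone_mask, cej = NULL, min_area = 200L,
                            sep_frac = 0.2) {
  stopifnot(is.matrix(bone_mask))
  bin <- as_binary(bone_mask)
  if (!any(bin != 0L)) stop("position undeterminable: empty bone mask")
  lab <- cpp_label8(bin)
  sizes <- tabulate(lab[lab > 0L])
  big <- which(sizes >= min_area)
  if (length(big) == 0L) big <- which.max(sizes)
  cents <- vapply(big, function(i) mean(which(lab == i, arr.ind = TRUE)[, 1]) - 1,
                  0)
  if (length(big) >= 2L) {
    if (diff(range(cents)) >= sep_frac * nrow(bin)) return("bitewing")
  }
  if (is.null(cej)) stop("position undeterminable: single bone area but no CEJ")
  if (is.matrix(cej)) cej <- connect_cej(cej)
  main <- big[which.max(sizes[big])]
  bone_row <- mean(which(lab == main, arr.ind = TRUE)[, 1]) - 1
  if (bone_row < mean(cej$y)) "maxilla" else "mandible"
}

#' Arrange a radiograph set into the full-mouth-series template
#'
#' Routes every radiograph to the top (maxillary), middle (bitewing) or
#' bottom (mandibular) row by its position and orders each row patient-right
#' to patient-left by the mean universal-number-derived arch coordinate of
#' the assigned FDI numbers (universal numbering snakes back along the
#' mandible, so the lower-row coordinate is reflected; the mean keeps
#' partially mis-numbered radiographs near their true slot). Radiographs whose rows overlap in tooth coverage are both
#' kept and flagged. Radiographs with no assignments land in `unplaced`.
#'
#' @param radiographs List of `list(id =, position =, assignments =)` where
#'   `assignments` is a list of `fdi_assignment`s or an integer vector of
#'   FDI numbers.
#' @return List of class `fms_template` with `top`, `middle`, `bottom` (each
#'   a list of slots `list(id, fdi)`), `unplaced` (character ids), and an
#'   `overlaps` attribute.
#' @export
arrange_fms <- function(radiographs) {
  rows <- list(maxilla = list(), bitewing = list(), mandible = list())
  unplaced <- character(0)
  for (r in radiographs) {
    fdi <- r$assignments
    if (is.list(fdi)) fdi <- vapply(fdi, function(a)
      if (inherits(a, "fdi_assignment")) a$fdi else as.integer(a), 0L)
    fdi <- as.integer(fdi)
    if (length(fdi) == 0L || all(is.na(fdi))) {
      unplaced <- c(unplaced, r$id)
      next
    }
    fdi <- fdi[!is.na(fdi)]
    stopifnot(r$position %in% names(rows))
    # patient-right -> patient-left coordinate: universal 1..16 runs that way
    # along the maxilla, 32..17 along the mandible (the sequence snakes back)
    uni <- fdi_to_universal(fdi)
    rows[[r$position]][[length(rows[[r$position]]) + 1L]] <-
      list(id = r$id, fdi = sort(fdi),
           key = mean(ifelse(uni <= 16L, uni, 49L - uni)))
  }
  order_row <- function(slots) {
    if (length(slots) == 0L) return(slots)
    keys <- vapply(slots, `[[`, 0, "key")
    ids <- vapply(slots, `[[`, "", "id")
    slots <- slots[order(keys, ids)]
    lapply(slots, function(s) s[c("id", "fdi")])
  }
  overlaps <- character(0)
  for (nm in names(rows)) {
    slots <- rows[[nm]]
    if (length(slots) > 1L) {
      for (i in seq_along(slots)) for (j in seq_along(slots)) {
        if (i < j && length(intersect(slots[[i]]$fdi, slots[[j]]$fdi)))
          overlaps <- c(overlaps,
                        sprintf("%s/%s", slots[[i]]$id, slots[[j]]$id))
      }
    }
    rows[[nm]] <- order_row(slots)
  }
  structure(list(top = rows$maxilla, middle = rows$bitewing,
                 bottom = rows$mandible, unplaced = unplaced),
            class = "fms_template", overlaps = overlaps)
}

#' @export
print.fms_template <- function(x, ...) {
  fmt <- function(slots) paste(vapply(slots, `[[`, "", "id"), collapse = " | ")
  cat("FMS template\n",
      "  top (maxillary):   ", fmt(x$top), "\n",
      "  middle (bitewing): ", fmt(x$middle), "\n",
      "  bottom (mandibular):", fmt(x$bottom), "\n", sep = "")
  if (length(x$unplaced))
    cat("  unplaced:", paste(x$unplaced, collapse = ", "), "\n")
  invisible(x)
}
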