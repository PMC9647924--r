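# The FDI-labeled tooth repository used as the matching reference: build it
# from annotated panoramics, persist it as manifest + crop PNGs, query FDI
# arithmetic.

#' Validate FDI tooth numbers
#'
#' @param fdi Integer vector.
#' @return Logical vector: is each a valid two-digit FDI code (quadrant 1-4,
#'   position 1-8)?
#' @export
is_valid_fdi <- function(fdi) fdi %in% ALL_FDI

#' Convert FDI numbers to the US universal system
#'
#' Universal numbering runs 1-32 starting at the upper-right third molar
#' (FDI 18 -> 1, 11 -> 8, 21 -> 9, 28 -> 16, 38 -> 17, 31 -> 24, 41 -> 25,
#' 48 -> 32), linear within each quadrant.
#'
#' @param fdi Vector of FDI numbers.
#' @return Integer vector in 1..32.
#' @export
fdi_to_universal <- function(fdi) {
  if (!all(is_valid_fdi(fdi))) stop("invalid FDI number: ",
                                    paste(fdi[!is_valid_fdi(fdi)], collapse = ", "))
  q <- fdi %/% 10L; i <- fdi %% 10L
  as.integer(ifelse(q == 1L, 9L - i,
             ifelse(q == 2L, 8L + i,
             ifelse(q == 3L, 25L - i, 24L + i))))
}

new_repository <- function(entries) {
  structure(list(entries = entries, manifest_version = "1"),
            class = "tooth_repository")
}

#' Build a tooth repository from annotated panoramic images
#'
#' Each annotated tooth contributes one entry: the crop is the polygon's
#' bounding-box patch, labeled with its FDI number. Duplicate FDI labels are
#' allowed (and useful: majority voting benefits from several exemplars per
#' tooth).
#'
#' @param panoramics List of `list(image =, annotations =, source_id =)`,
#'   where `annotations` is a list of `list(polygon = n x 2 matrix of (x, y),
#'   fdi = int)` (0-based coordinates) or a data frame of boxes with columns
#'   `x0, y0, x1, y1, fdi`.
#' @return A `tooth_repository`; FDI numbers with zero entries are reported
#'   in `attr(, "uncovered")`.
#' @export
build_repository <- function(panoramics) {
  entries <- list()
  for (p in panoramics) {
    src <- p$source_id %||% "panoramic"
    ann <- p$annotations
    if (is.data.frame(ann)) {
      ann <- lapply(seq_len(nrow(ann)), function(i)
        list(polygon = cbind(c(ann$x0[i], ann$x1[i] - 1L),
                             c(ann$y0[i], ann$y1[i] - 1L)),
             fdi = ann$fdi[i]))
    }
    for (a in ann) {
      if (!is_valid_fdi(a$fdi))
        stop("invalid FDI number ", a$fdi, " in annotations of ", src)
      poly <- a$polygon
      x0 <- min(poly[, 1]); x1 <- max(poly[, 1])
      y0 <- min(poly[, 2]); y1 <- max(poly[, 2])
      if (x0 < 0 || y0 < 0 || x1 >= ncol(p$image) || y1 >= nrow(p$image))
        stop("polygon outside image in ", src)
      entries[[length(entries) + 1L]] <- list(
        crop = p$image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
        fdi = as.integer(a$fdi), source_id = src)
    }
  }
  repo <- new_repository(entries)
  covered <- unique(vapply(entries, `[[`, 0L, "fdi"))
  attr(repo, "uncovered") <- setdiff(ALL_FDI, covered)
  repo
}

#' @export
print.tooth_repository <- function(x, ...) {
  fdis <- vapply(x$entries, `[[`, 0L, "fdi")
  cat(sprintf("tooth_repository: %d entries, %d/32 FDI numbers covered\n",
              length(x$entries), length(unique(fdis))))
  invisible(x)
}

#' Save / load a tooth repository
#'
#' Directory layout: `manifest.json` plus `crops/*.png` (8-bit grayscale,
#' stored at native size since matching is multi-scale). The round trip is
#' lossless.
#'
#' @param repo A `tooth_repository`.
#' @param directory Target directory.
#' @return `save_repository` returns the manifest path invisibly;
#'   `load_repository` returns the repository.
#' @export
save_repository <- function(repo, directory) {
  stopifnot(inherits(repo, "tooth_repository"))
  dir.create(file.path(directory, "crops"), recursive = TRUE,
             showWarnings = FALSE)
  recs <- lapply(seq_along(repo$entries), function(i) {
    e <- repo$entries[[i]]
    f <- sprintf("crops/entry_%04d.png", i)
    png::writePNG(round(e$crop * 255) / 255, file.path(directory, f))
    list(file = f, fdi = e$fdi, source_id = e$source_id)
  })
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(list(manifest_version = repo$manifest_version,
                            entries = recs),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_repository
#' @export
load_repository <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", directory)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(man$entries, function(r) {
    f <- file.path(directory, r$file)
    if (!file.exists(f)) stop("missing crop file referenced by manifest: ", r$file)
    list(crop = png::readPNG(f), fdi = as.integer(r$fdi),
         source_id = r$source_id)
  })
  new_repository(entries)
}
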