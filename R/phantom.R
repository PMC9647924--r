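# Seeded phantom radiograph generator. Produces radiograph-like images with
# gold-standard masks, boxes, FDI labels, positions and bone-level fractions
# so that every downstream stage (extraction, matching, layout, perio,
# metrics) can be exercised and scored without clinical data.

ALL_FDI <- c(11:18, 21:28, 31:38, 41:48)

# Per-index (position in arch, 1..8) glyph geometry at unit scale, in pixels.
# Four shape families: incisor (1-2), canine (3), premolar (4-5), molar (6-8);
# crown width, root length, apex drift and an intensity-texture frequency all
# vary with the index so that every position in the arch is discriminable
# under normalized cross-correlation, not just the family.
GLYPH_PARAMS <- data.frame(
  index    = 1:8,
  family   = c("incisor", "incisor", "canine", "premolar", "premolar",
               "molar", "molar", "molar"),
  crown_w  = c(24, 21, 26, 30, 28, 42, 40, 36),
  crown_h  = c(34, 31, 38, 30, 28, 28, 27, 25),
  root_l   = c(64, 58, 74, 60, 56, 56, 52, 48),
  apex_dx  = c(5, -3, 9, 6, -7, 9, -9, 8),
  tex_freq = 1:8,
  tex_freq_x = c(2, 5, 3, 6, 4, 7, 2, 5),
  tex_phase = 0.4 * (1:8)
)

PAN_SCALE <- 0.75     # glyph scale on the panoramic relative to intraoral
TOOTH_GAP <- 10L      # inter-tooth gap on intraoral images, px
PAN_GAP <- 5L         # inter-tooth gap on the panoramic, px

# Standard full-mouth-series coverage: 7 maxillary + 7 mandibular periapicals
# and 4 bitewings.
PA_GROUPS_MAX  <- list(c(18, 17, 16), c(15, 14), 13, c(12, 11, 21, 22),
                       23, c(24, 25), c(26, 27, 28))
PA_GROUPS_MAND <- list(c(48, 47, 46), c(45, 44), 43, c(42, 41, 31, 32),
                       33, c(34, 35), c(36, 37, 38))
BW_GROUPS <- list(list(max = c(16, 17, 18), mand = c(46, 47, 48)),
                  list(max = c(14, 15),     mand = c(44, 45)),
                  list(max = c(24, 25),     mand = c(34, 35)),
                  list(max = c(26, 27, 28), mand = c(36, 37, 38)))

fdi_ok <- function(fdi) fdi %in% ALL_FDI

#' Configuration for the phantom case generator
#'
#' @param image_size `c(height, width)` of all generated rasters (default
#'   512 x 512, the pipeline's working resolution).
#' @param quadrants_present Subset of `1:4` (FDI quadrants) rendered.
#' @param missing_fdi FDI numbers of absent teeth.
#' @param scale_jitter Per-tooth multiplicative size jitter, a fraction in
#'   `[0, 0.5]`: each rendered tooth is scaled by `1 + U(-s, s)`.
#' @param position_jitter Per-tooth placement jitter in pixels (uniform
#'   integer offsets in both axes).
#' @param bone_level_fraction Fraction of root length from CEJ to the alveolar
#'   crest, in `[0, 1]`: either a scalar for all teeth or a vector named by
#'   FDI number. The default 0.10 sits below the Stage-1 threshold, so
#'   default phantoms are periodontally healthy.
#' @param noise_sigma Standard deviation of additive Gaussian gray-level
#'   noise on images (masks stay exact).
#' @param seed Integer seed; generation with identical config and seed is
#'   bit-identical.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(512L, 512L),
                           quadrants_present = 1:4,
                           missing_fdi = integer(0),
                           scale_jitter = 0,
                           position_jitter = 0,
                           bone_level_fraction = 0.10,
                           noise_sigma = 0,
                           seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 128L),
            all(quadrants_present %in% 1:4),
            scale_jitter >= 0, scale_jitter <= 0.5,
            position_jitter >= 0,
            all(bone_level_fraction >= 0), all(bone_level_fraction <= 1),
            noise_sigma >= 0, length(seed) == 1L)
  if (length(missing_fdi) && !all(fdi_ok(missing_fdi)))
    stop("invalid FDI in missing_fdi: ",
         paste(missing_fdi[!fdi_ok(missing_fdi)], collapse = ", "))
  if (length(bone_level_fraction) > 1L &&
      !all(names(bone_level_fraction) %in% as.character(ALL_FDI)))
    stop("bone_level_fraction vector must be named by FDI numbers")
  structure(list(image_size = as.integer(image_size),
                 quadrants_present = sort(unique(as.integer(quadrants_present))),
                 missing_fdi = sort(unique(as.integer(missing_fdi))),
                 scale_jitter = scale_jitter,
                 position_jitter = as.numeric(position_jitter),
                 bone_level_fraction = bone_level_fraction,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

blf_for <- function(config, fdi) {
  b <- config$bone_level_fraction
  if (length(b) == 1L && is.null(names(b))) return(unname(b))
  v <- b[as.character(fdi)]
  ifelse(is.na(v), 0.10, unname(v))
}

# Base-orientation glyph raster (crown at top, root at bottom = mandibular
# right). Returns intensity patch, binary mask and the 0-based CEJ row.
render_glyph_base <- function(index, scale, seed) {
  p <- GLYPH_PARAMS[index, ]
  jit <- with_seed(seed * 64 + index,
                   c(runif(1, -0.03, 0.03), runif(1, -0.3, 0.3)))
  cw <- p$crown_w * (1 + jit[1]) * scale
  ch_px <- max(4L, as.integer(round(p$crown_h * scale)))
  rl_px <- max(6L, as.integer(round(p$root_l * scale)))
  H <- ch_px + rl_px
  W <- max(7L, as.integer(round(cw + 4 * scale)))
  cx <- (W - 1) / 2
  xs <- 0:(W - 1)
  mask <- matrix(FALSE, H, W)
  notch_h <- max(2L, round(0.3 * ch_px))
  notch_w <- max(1.5, 2.5 * scale)
  for (r in seq_len(H)) {
    y <- r - 1
    if (y < ch_px) {                      # crown
      frac <- y / max(1L, ch_px - 1L)
      hw <- switch(p$family,
                   incisor  = cw * (0.72 + 0.28 * frac) / 2,
                   canine   = cw * (0.22 + 0.78 * frac) / 2,
                   cw / 2)
      keep <- abs(xs - cx) <= hw
      if (p$family %in% c("premolar", "molar") && y < notch_h) {
        depth <- notch_w * (1 - y / notch_h)
        centers <- if (p$family == "molar") cx + c(-1, 1) * cw / 4 else cx
        for (nc in centers) keep[abs(xs - nc) < depth] <- FALSE
      }
      mask[r, keep] <- TRUE
    } else {                              # root
      t <- (y - ch_px) / max(1L, rl_px - 1L)
      drift <- p$apex_dx * scale * t
      if (p$family == "molar" && t >= 0.25) {
        sep <- 0.26 * cw
        hw <- (0.16 * cw * (1 - t) + 1.2 * t)
        for (ctr in cx + drift + c(-sep, sep))
          mask[r, abs(xs - ctr) <= hw] <- TRUE
      } else if (p$index == 4L && t >= 0.45) {
        # first premolar: bifurcated root, narrower and later than molars
        sep <- 0.17 * cw
        hw <- (0.12 * cw * (1 - t) + 1.0 * t)
        for (ctr in cx + drift + c(-sep, sep))
          mask[r, abs(xs - ctr) <= hw] <- TRUE
      } else {
        w0 <- if (p$family == "molar") 0.78 * cw else 0.62 * cw
        hw <- (w0 * (1 - t) + 3 * scale * t) / 2
        mask[r, abs(xs - (cx + drift)) <= hw] <- TRUE
      }
    }
  }
  yrel <- matrix((seq_len(H) - 1) / (H - 1), H, W)
  xrel <- matrix(rep((xs) / (W - 1), each = H), H, W)
  tex <- 0.62 + 0.30 * (0.5 + 0.5 * cos(2 * pi * p$tex_freq * yrel +
                                          p$tex_phase + jit[2])) *
                        (0.55 + 0.45 * cos(2 * pi * p$tex_freq_x * xrel + 0.7)) +
         0.04 * (xrel - 0.5)
  patch <- matrix(0, H, W)
  patch[mask] <- clamp(tex[mask], 0.55, 1)
  list(patch = patch, mask = mask, cej_row = ch_px, height = H, width = W)
}

#' Render a single synthetic tooth glyph
#'
#' Deterministic tooth-shaped patch for a given FDI number. Left-quadrant
#' glyphs are horizontal mirrors of their right-quadrant counterparts
#' (midline symmetry); maxillary glyphs are vertical flips of mandibular ones
#' (roots point away from the occlusal plane).
#'
#' @param fdi FDI tooth number (11-18, 21-28, 31-38, 41-48).
#' @param scale Positive size factor (1 = intraoral working scale).
#' @param seed Integer controlling mild within-class shape variation.
#' @return List with `patch` (intensity matrix, background 0), `mask`
#'   (logical), `outline` (boundary contour, 0-based x/y), `cej_row` (0-based
#'   row of the crown/root junction within the patch), `fdi`.
#' @export
generate_tooth_glyph <- function(fdi, scale = 1, seed = 1L) {
  if (length(fdi) != 1L || !fdi_ok(fdi))
    stop("invalid FDI number: ", fdi)
  stopifnot(scale > 0)
  q <- fdi %/% 10L
  g <- render_glyph_base(fdi %% 10L, scale, seed)
  if (q %in% c(2L, 3L)) { g$patch <- flip_lr(g$patch); g$mask <- flip_lr(g$mask) }
  if (q %in% c(1L, 2L)) {                 # maxilla: root up
    g$patch <- flip_ud(g$patch); g$mask <- flip_ud(g$mask)
    g$cej_row <- g$height - 1L - g$cej_row
  }
  g$fdi <- as.integer(fdi)
  g$outline <- extract_contours(g$mask * 1L)[[1]]
  g
}

# ---- case assembly -----------------------------------------------------

# Place a glyph patch on a canvas (max-composited); returns updated canvas
# pieces plus the realised bounding box of the glyph mask in canvas coords.
place_glyph <- function(canvas, tooth_mask, g, top, left) {
  H <- g$height; W <- g$width
  rows <- (top + 1):(top + H); cols <- (left + 1):(left + W)
  canvas[rows, cols] <- pmax(canvas[rows, cols], g$patch)
  tooth_mask[rows, cols] <- tooth_mask[rows, cols] | g$mask
  px <- which(g$mask, arr.ind = TRUE)
  box <- new_box(left + min(px[, 2]) - 1L, top + min(px[, 1]) - 1L,
                 left + max(px[, 2]), top + max(px[, 1]))
  list(canvas = canvas, tooth_mask = tooth_mask, box = box)
}

# Render one intraoral image (periapical arch or bitewing) for the given
# teeth. `arches` is a list of lists(fdi vector, cej_y, direction) where
# direction +1 means roots extend downward (mandible) and -1 upward.
render_intraoral <- function(config, id, kind, position, arches) {
  hw <- config$image_size
  img <- matrix(0, hw[1], hw[2])
  tooth_mask <- matrix(FALSE, hw[1], hw[2])
  bone_mask <- matrix(0L, hw[1], hw[2])
  cej_mask <- matrix(0L, hw[1], hw[2])
  teeth <- NULL
  for (arch in arches) {
    fdis <- arch$fdi
    glyphs <- list(); jit <- list()
    for (f in fdis) {
      s <- 1 + if (config$scale_jitter > 0)
        runif(1, -config$scale_jitter, config$scale_jitter) else 0
      dxy <- if (config$position_jitter > 0)
        round(runif(2, -config$position_jitter, config$position_jitter)) else c(0, 0)
      glyphs[[as.character(f)]] <- generate_tooth_glyph(f, s, config$seed)
      jit[[as.character(f)]] <- dxy
    }
    present <- fdis[!(fdis %in% config$missing_fdi) &
                      (fdis %/% 10L) %in% config$quadrants_present]
    widths <- vapply(glyphs, function(g) g$width, 0L)
    total <- sum(widths) + TOOTH_GAP * (length(fdis) - 1L)
    left <- max(0L, as.integer(round((hw[2] - total) / 2)))
    cursor <- left
    band_cols <- c(); crest_rows <- c()
    for (f in fdis) {
      g <- glyphs[[as.character(f)]]
      if (f %in% present) {
        dxy <- jit[[as.character(f)]]
        cej_y <- as.integer(arch$cej_y + dxy[2])
        top <- cej_y - g$cej_row
        x0 <- as.integer(cursor + dxy[1])
        x0 <- clamp(x0, 0L, hw[2] - g$width)
        top <- clamp(top, 0L, hw[1] - g$height)
        pl <- place_glyph(img, tooth_mask, g, top, x0)
        img <- pl$canvas; tooth_mask <- pl$tooth_mask
        root_len <- if (arch$dir > 0) (top + g$height - 1L) - cej_y
                    else cej_y - top
        f_blf <- blf_for(config, f)
        crest <- cej_y + arch$dir * as.integer(round(f_blf * root_len))
        apex_y <- if (arch$dir > 0) top + g$height - 1L else top
        # per-tooth CEJ segment across its column span (+ half gaps)
        c0 <- max(0L, pl$box$x0 - TOOTH_GAP %/% 2L)
        c1 <- min(hw[2] - 1L, pl$box$x1 - 1L + TOOTH_GAP %/% 2L)
        cej_mask[cej_y + 1L, (c0 + 1L):(c1 + 1L)] <- 1L
        # bone band under this tooth, from crest away from the crown
        if (arch$dir > 0) {
          b0 <- crest; b1 <- min(hw[1] - 1L, cej_y + root_len + 25L)
        } else {
          b0 <- max(0L, cej_y - root_len - 25L); b1 <- crest
        }
        bone_mask[(b0 + 1L):(b1 + 1L), (c0 + 1L):(c1 + 1L)] <- 1L
        gold_y <- sort(c(apex_y, cej_y))
        teeth <- rbind(teeth, data.frame(
          fdi = as.integer(f), x0 = pl$box$x0, y0 = gold_y[1],
          x1 = pl$box$x1, y1 = gold_y[2] + 1L,
          full_y0 = pl$box$y0, full_y1 = pl$box$y1,
          cej_y = cej_y, apex_y = apex_y, crest_y = crest,
          root_len = root_len, bone_level_fraction = f_blf,
          arch = if (arch$dir > 0) "mandible" else "maxilla"))
      }
      cursor <- cursor + g$width + TOOTH_GAP
    }
  }
  img <- pmax(img, 0.4 * (bone_mask & !tooth_mask))
  if (config$noise_sigma > 0)
    img <- clamp(img + rnorm(length(img), 0, config$noise_sigma), 0, 1)
  img <- round(img * 255) / 255
  list(id = id, kind = kind, position = position, image = img,
       tooth_mask = as_binary(tooth_mask * 1L), bone_mask = bone_mask,
       cej_mask = cej_mask, teeth = teeth)
}

render_panoramic <- function(config) {
  hw <- config$image_size
  img <- matrix(0, hw[1], hw[2])
  tooth_mask <- matrix(FALSE, hw[1], hw[2])
  teeth <- NULL
  occlusal <- as.integer(round(hw[1] / 2))
  for (arch in list(list(fdi = c(18:11, 21:28), dir = -1L, edge = occlusal - 16L),
                    list(fdi = c(48:41, 31:38), dir = +1L, edge = occlusal + 16L))) {
    glyphs <- lapply(arch$fdi, function(f) {
      s <- PAN_SCALE * (1 + if (config$scale_jitter > 0)
        runif(1, -config$scale_jitter, config$scale_jitter) else 0)
      generate_tooth_glyph(f, s, config$seed)
    })
    names(glyphs) <- as.character(arch$fdi)
    widths <- vapply(glyphs, function(g) g$width, 0L)
    total <- sum(widths) + PAN_GAP * (length(arch$fdi) - 1L)
    cursor <- max(0L, as.integer(round((hw[2] - total) / 2)))
    for (f in arch$fdi) {
      g <- glyphs[[as.character(f)]]
      present <- !(f %in% config$missing_fdi) &&
        (f %/% 10L) %in% config$quadrants_present
      if (present) {
        dxy <- if (config$position_jitter > 0)
          round(runif(2, -config$position_jitter, config$position_jitter)) else c(0, 0)
        top <- if (arch$dir < 0) arch$edge - g$height else arch$edge
        top <- clamp(as.integer(top + dxy[2]), 0L, hw[1] - g$height)
        x0 <- clamp(as.integer(cursor + dxy[1]), 0L, hw[2] - g$width)
        pl <- place_glyph(img, tooth_mask, g, top, x0)
        img <- pl$canvas; tooth_mask <- pl$tooth_mask
        teeth <- rbind(teeth, cbind(pl$box, data.frame(
          fdi = as.integer(f),
          arch = if (arch$dir < 0) "maxilla" else "mandible")))
      }
      cursor <- cursor + g$width + PAN_GAP
    }
  }
  if (config$noise_sigma > 0)
    img <- clamp(img + rnorm(length(img), 0, config$noise_sigma), 0, 1)
  img <- round(img * 255) / 255
  list(image = img, tooth_mask = as_binary(tooth_mask * 1L), teeth = teeth)
}

#' Generate a complete phantom radiograph case
#'
#' Renders a panoramic radiograph, up to 14 periapicals (7 maxillary + 7
#' mandibular) and 4 bitewings from the synthetic tooth glyphs, together with
#' gold tooth/bone/CEJ masks, per-tooth boxes and FDI labels, radiograph
#' positions, and known bone-level fractions. Maxillary periapicals place the
#' bone band above the CEJ line, mandibular below, bitewings have two bands
#' flanking a double CEJ.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom_case` with elements `panoramic`,
#'   `periapicals`, `bitewings`, `gold_chart` and `config`.
#' @export
generate_phantom_case <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    pano <- render_panoramic(config)
    cy <- as.integer(round(config$image_size[1] / 2))
    pas <- list()
    for (i in seq_along(PA_GROUPS_MAX)) {
      r <- render_intraoral(config, sprintf("pa_max_%d", i), "periapical",
                            "maxilla",
                            list(list(fdi = PA_GROUPS_MAX[[i]], cej_y = cy, dir = -1L)))
      if (!is.null(r$teeth)) pas[[length(pas) + 1L]] <- r
    }
    for (i in seq_along(PA_GROUPS_MAND)) {
      r <- render_intraoral(config, sprintf("pa_mand_%d", i), "periapical",
                            "mandible",
                            list(list(fdi = PA_GROUPS_MAND[[i]], cej_y = cy, dir = +1L)))
      if (!is.null(r$teeth)) pas[[length(pas) + 1L]] <- r
    }
    bws <- list()
    cej_u <- as.integer(round(config$image_size[1] * 0.39))
    cej_l <- as.integer(round(config$image_size[1] * 0.61))
    for (i in seq_along(BW_GROUPS)) {
      r <- render_intraoral(config, sprintf("bw_%d", i), "bitewing", "bitewing",
                            list(list(fdi = BW_GROUPS[[i]]$max, cej_y = cej_u, dir = -1L),
                                 list(fdi = BW_GROUPS[[i]]$mand, cej_y = cej_l, dir = +1L)))
      if (!is.null(r$teeth)) bws[[length(bws) + 1L]] <- r
    }
    chart <- data.frame(
      fdi = ALL_FDI,
      present = (ALL_FDI %/% 10L) %in% config$quadrants_present &
        !(ALL_FDI %in% config$missing_fdi),
      bone_level_fraction = blf_for(config, ALL_FDI))
    structure(list(panoramic = pano, periapicals = pas, bitewings = bws,
                   gold_chart = chart, config = config),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case: %d periapicals, %d bitewings, %d/32 teeth present (seed %d)\n",
              length(x$periapicals), length(x$bitewings),
              sum(x$gold_chart$present), x$config$seed))
  invisible(x)
}

# ---- persistence -------------------------------------------------------

write_png_gray <- function(m, path) png::writePNG(m, path)
write_png_mask <- function(m, path) png::writePNG(m * 1.0, path)

#' Write a phantom case to disk
#'
#' Images and masks go out as 8-bit grayscale PNGs (masks 0/255) plus a
#' `case_manifest.json` carrying labels, gold boxes, positions, bone-level
#' fractions, the seed and a config echo: everything needed to reload the
#' case losslessly with [read_case()].
#'
#' @param case A `phantom_case`.
#' @param directory Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_case <- function(case, directory) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_png_gray(case$panoramic$image, file.path(directory, "panoramic.png"))
  write_png_mask(case$panoramic$tooth_mask,
                 file.path(directory, "panoramic_tooth.png"))
  img_rec <- function(im) {
    base <- im$id
    write_png_gray(im$image, file.path(directory, paste0(base, ".png")))
    for (k in c("tooth", "bone", "cej"))
      write_png_mask(im[[paste0(k, "_mask")]],
                     file.path(directory, paste0(base, "_", k, ".png")))
    list(id = im$id, kind = im$kind, position = im$position,
         image = paste0(base, ".png"),
         tooth_mask = paste0(base, "_tooth.png"),
         bone_mask = paste0(base, "_bone.png"),
         cej_mask = paste0(base, "_cej.png"),
         teeth = im$teeth)
  }
  manifest <- list(
    format = "toothchart_phantom_case",
    version = "1",
    seed = case$config$seed,
    config = unclass(case$config),
    panoramic = list(image = "panoramic.png", tooth_mask = "panoramic_tooth.png",
                     teeth = case$panoramic$teeth),
    intraoral = lapply(c(case$periapicals, case$bitewings), img_rec),
    gold_chart = case$gold_chart)
  path <- file.path(directory, "case_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

coerce_teeth_df <- function(df) {
  if (is.null(df) || length(df) == 0L) return(NULL)
  df <- as.data.frame(df)
  for (cl in intersect(names(df), c("fdi", "x0", "y0", "x1", "y1", "full_y0",
                                    "full_y1", "cej_y", "apex_y", "crest_y",
                                    "root_len")))
    df[[cl]] <- as.integer(df[[cl]])
  df
}

#' Read a phantom case written by [write_case()]
#'
#' @param directory Directory containing `case_manifest.json`.
#' @return A `phantom_case`.
#' @export
read_case <- function(directory) {
  path <- file.path(directory, "case_manifest.json")
  if (!file.exists(path)) stop("no case_manifest.json in ", directory)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  rd_img <- function(f) png::readPNG(file.path(directory, f))
  rd_mask <- function(f) as_binary(png::readPNG(file.path(directory, f)))
  cfg <- man$config
  config <- phantom_config(image_size = cfg$image_size,
                           quadrants_present = cfg$quadrants_present %||% integer(0),
                           missing_fdi = cfg$missing_fdi %||% integer(0),
                           scale_jitter = cfg$scale_jitter,
                           position_jitter = cfg$position_jitter,
                           bone_level_fraction =
                             if (!is.null(names(cfg$bone_level_fraction)))
                               unlist(cfg$bone_level_fraction)
                             else cfg$bone_level_fraction,
                           noise_sigma = cfg$noise_sigma, seed = cfg$seed)
  pano <- list(image = rd_img(man$panoramic$image),
               tooth_mask = rd_mask(man$panoramic$tooth_mask),
               teeth = coerce_teeth_df(man$panoramic$teeth))
  intr <- lapply(seq_len(NROW(man$intraoral)), function(i) {
    rec <- if (is.data.frame(man$intraoral)) lapply(man$intraoral, `[[`, i)
           else man$intraoral[[i]]
    list(id = rec$id, kind = rec$kind, position = rec$position,
         image = rd_img(rec$image), tooth_mask = rd_mask(rec$tooth_mask),
         bone_mask = rd_mask(rec$bone_mask), cej_mask = rd_mask(rec$cej_mask),
         teeth = coerce_teeth_df(rec$teeth))
  })
  chart <- as.data.frame(man$gold_chart)
  chart$fdi <- as.integer(chart$fdi)
  structure(list(panoramic = pano,
                 periapicals = Filter(function(x) x$kind == "periapical", intr),
                 bitewings = Filter(function(x) x$kind == "bitewing", intr),
                 gold_chart = chart, config = config),
            class = "phantom_case")
}
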