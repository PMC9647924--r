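test_that("glyph generation is deterministic and midline-mirrored", {
  a <- generate_tooth_glyph(11, 1.0, seed = 4)
  b <- generate_tooth_glyph(11, 1.0, seed = 4)
  expect_identical(a$patch, b$patch)

  left <- generate_tooth_glyph(21, 1.0, seed = 4)
  expect_identical(left$patch, a$patch[, rev(seq_len(ncol(a$patch)))])

  # maxillary glyphs are upside-down mandibular ones
  up <- generate_tooth_glyph(14, 1.0, seed = 4)
  dn <- generate_tooth_glyph(44, 1.0, seed = 4)
  expect_identical(up$patch, dn$patch[rev(seq_len(nrow(dn$patch))), ])

  expect_error(generate_tooth_glyph(19), "invalid FDI.*19")
  expect_error(generate_tooth_glyph(0), "invalid FDI")
})

test_that("every tooth position scores itself above every other glyph", {
  fdis <- c(11:18, 21:28, 31:38, 41:48)
  glyphs <- lapply(fdis, function(f) generate_tooth_glyph(f, 1.0, seed = 3))
  S <- matrix(NA_real_, 32, 32)
  for (i in 1:32) for (j in 1:32)
    S[i, j] <- match_score(glyphs[[i]]$patch, glyphs[[j]]$patch, 1)$score
  for (i in 1:32) expect_true(all(S[i, i] > S[i, -i]),
                              label = sprintf("diagonal dominance for FDI %d", fdis[i]))
})

test_that("a default phantom case has the full FMS structure", {
  case <- tc_case(seed = 7)
  expect_length(case$periapicals, 14L)
  expect_length(case$bitewings, 4L)
  expect_equal(sum(case$gold_chart$present), 32L)
  expect_equal(nrow(case$panoramic$teeth), 32L)
  expect_setequal(case$panoramic$teeth$fdi, c(11:18, 21:28, 31:38, 41:48))

  # positions: 7 maxillary, 7 mandibular, 4 bitewing
  pos <- vapply(case$periapicals, `[[`, "", "position")
  expect_equal(sum(pos == "maxilla"), 7L)
  expect_equal(sum(pos == "mandible"), 7L)
  expect_true(all(vapply(case$bitewings, `[[`, "", "position") == "bitewing"))

  # maxillary bone band above the CEJ, mandibular below
  pa_max <- case$periapicals[[1]]
  bone_rows <- which(rowSums(pa_max$bone_mask) > 0) - 1
  expect_lt(mean(bone_rows), mean(pa_max$teeth$cej_y))
  pa_mand <- case$periapicals[[8]]
  bone_rows2 <- which(rowSums(pa_mand$bone_mask) > 0) - 1
  expect_gt(mean(bone_rows2), mean(pa_mand$teeth$cej_y))

  # gold boxes are in bounds and labels valid
  for (im in c(case$periapicals, case$bitewings)) {
    expect_true(all(is_valid_fdi(im$teeth$fdi)))
    expect_true(all(im$teeth$x0 >= 0 & im$teeth$y0 >= 0 &
                      im$teeth$x1 <= 512 & im$teeth$y1 <= 512))
  }
})

test_that("rendered glyph pixels lie inside their gold full-extent boxes", {
  case <- tc_case(seed = 7)
  dominant_comp <- function(lab, y0, y1, x0, x1) {
    sub <- lab[(y0 + 1):y1, (x0 + 1):x1]
    as.integer(names(which.max(table(sub[sub > 0]))))
  }
  pt <- case$panoramic$teeth
  lab <- label8_r(case$panoramic$tooth_mask)
  for (i in seq_len(nrow(pt))) {
    comp <- dominant_comp(lab, pt$y0[i], pt$y1[i], pt$x0[i], pt$x1[i])
    px <- which(lab == comp, arr.ind = TRUE)
    inside <- px[, 1] - 1 >= pt$y0[i] & px[, 1] - 1 < pt$y1[i] &
      px[, 2] - 1 >= pt$x0[i] & px[, 2] - 1 < pt$x1[i]
    expect_gte(mean(inside), 0.9)
  }
  for (im in case$periapicals[c(1, 8)]) {
    labi <- label8_r(im$tooth_mask)
    for (i in seq_len(nrow(im$teeth))) {
      tt <- im$teeth[i, ]
      comp <- dominant_comp(labi, tt$full_y0, tt$full_y1, tt$x0, tt$x1)
      px <- which(labi == comp, arr.ind = TRUE)
      inside <- px[, 1] - 1 >= tt$full_y0 & px[, 1] - 1 < tt$full_y1 &
        px[, 2] - 1 >= tt$x0 & px[, 2] - 1 < tt$x1
      expect_gte(mean(inside), 0.9)
    }
  }
})

test_that("missing teeth vanish from the panoramic, periapical and chart", {
  case <- tc_case(seed = 6, missing_fdi = 36)
  expect_false(36 %in% case$panoramic$teeth$fdi)
  pa_fdis <- unlist(lapply(case$periapicals, function(p) p$teeth$fdi))
  expect_false(36 %in% pa_fdis)
  expect_false(case$gold_chart$present[case$gold_chart$fdi == 36])
  expect_equal(sum(case$gold_chart$present), 31L)
})

test_that("case generation is bit-identical under a fixed seed", {
  c1 <- generate_phantom_case(phantom_config(seed = 19))
  c2 <- generate_phantom_case(phantom_config(seed = 19))
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_case(c1, d1); write_case(c2, d2)
  expect_identical(readBin(file.path(d1, "case_manifest.json"), "raw", 1e7),
                   readBin(file.path(d2, "case_manifest.json"), "raw", 1e7))
  expect_identical(readBin(file.path(d1, "panoramic.png"), "raw", 1e7),
                   readBin(file.path(d2, "panoramic.png"), "raw", 1e7))
})

test_that("write_case / read_case round-trips a case losslessly", {
  case <- tc_case(seed = 7)
  d <- withr::local_tempdir()
  write_case(case, d)
  back <- read_case(d)
  expect_identical(back$panoramic$image, case$panoramic$image)
  expect_identical(back$panoramic$teeth, case$panoramic$teeth)
  expect_length(back$periapicals, length(case$periapicals))
  for (i in seq_along(case$periapicals)) {
    expect_identical(back$periapicals[[i]]$teeth, case$periapicals[[i]]$teeth)
    expect_identical(back$periapicals[[i]]$tooth_mask,
                     case$periapicals[[i]]$tooth_mask)
  }
  expect_equal(back$gold_chart, case$gold_chart)
})

test_that("an empty quadrant set yields zero intraoral images but a valid manifest", {
  case <- generate_phantom_case(phantom_config(quadrants_present = integer(0),
                                               seed = 2))
  expect_length(case$periapicals, 0L)
  expect_length(case$bitewings, 0L)
  expect_equal(sum(case$gold_chart$present), 0L)
  d <- withr::local_tempdir()
  write_case(case, d)
  back <- read_case(d)
  expect_length(back$periapicals, 0L)
})

test_that("phantom_config rejects invalid input", {
  expect_error(phantom_config(missing_fdi = 19), "invalid FDI")
  expect_error(phantom_config(scale_jitter = 0.9))
  expect_error(phantom_config(bone_level_fraction = 1.2))
})
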