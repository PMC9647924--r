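test_that("preprocess_image resizes to the working resolution and heatmap-encodes", {
  img <- matrix(runif(1000 * 800), 1000, 800)
  out <- preprocess_image(img)
  expect_equal(dim(out), c(512L, 512L))

  same <- matrix(runif(512 * 512), 512, 512)
  expect_identical(preprocess_image(same), same)

  flat <- matrix(0.5, 64, 64)
  hm <- preprocess_image(flat, c(64, 64), heatmap = TRUE)
  expect_equal(dim(hm), c(64, 64, 3))
  for (ch in 1:3) expect_equal(length(unique(as.vector(hm[, , ch]))), 1L)

  # monotone in intensity: luminance of the mapped ramp is non-decreasing
  ramp <- matrix(seq(0, 1, length.out = 64), 1, 64)
  hr <- preprocess_image(ramp, c(1, 64), heatmap = TRUE)
  lum <- 0.2126 * hr[1, , 1] + 0.7152 * hr[1, , 2] + 0.0722 * hr[1, , 3]
  expect_true(all(diff(lum) > -0.01))  # monotone up to palette quantization
  expect_gt(lum[64] - lum[1], 0.5)

  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "zero dimension")
})

test_that("clean_mask keeps large components, drops specks, is idempotent", {
  clean <- matrix(0L, 64, 64); clean[10:40, 10:40] <- 1L
  expect_identical(clean_mask(clean, sigma = 0, min_area = 0), clean)

  m <- matrix(0, 64, 64)
  m[5:44, 5:29] <- 1                                   # 1000-px blob
  m[2, 60] <- 1; m[60, c(2, 3)] <- 1; m[50, 55] <- 1   # specks
  out <- clean_mask(m, sigma = 0, min_area = 10)
  expect_equal(max(label8_r(out)), 1L)
  expect_equal(sum(out), 40L * 25L)

  expect_identical(clean_mask(matrix(0, 8, 8)), matrix(0L, 8, 8))

  # idempotence on soft rasters, exercised over random blob images
  set.seed(42)
  for (rep in 1:25) {
    base <- matrix(0, 48, 48)
    for (b in 1:3) {
      x <- sample(4:36, 1); y <- sample(4:36, 1)
      base[y:(y + sample(4:10, 1)), x:(x + sample(4:10, 1))] <- 1
    }
    soft <- clamp_test(base * 0.85 + matrix(runif(48 * 48, 0, 0.35), 48, 48))
    once <- clean_mask(soft)
    expect_identical(clean_mask(once), once)
  }
})

test_that("extract_contours returns one boundary per component, largest first", {
  rect <- matrix(0L, 20, 30); rect[5:10, 8:20] <- 1L
  ct <- extract_contours(rect)
  expect_length(ct, 1L)
  # every contour point lies on the component border
  border <- rect
  border[6:9, 9:19] <- 0L
  expect_true(all(border[cbind(ct[[1]][, "y"] + 1, ct[[1]][, "x"] + 1)] == 1L))

  two <- matrix(0L, 30, 30)
  two[2:4, 2:4] <- 1L          # 9 px
  two[10:20, 10:25] <- 1L      # larger
  cts <- extract_contours(two)
  expect_length(cts, 2L)
  expect_true(min(cts[[1]][, "x"]) == 9)  # larger blob traced first

  expect_identical(extract_contours(matrix(0L, 5, 5)), list())
})

test_that("contour count equals the 8-connected component count (labeling oracle)", {
  set.seed(7)
  for (rep in 1:200) {
    m <- matrix(as.integer(runif(32 * 32) < 0.25), 32, 32)
    expect_length(extract_contours(m), max(label8_r(m)))
  }
})

test_that("connect_cej bridges short gaps and follows the mask centroid", {
  line <- matrix(0L, 64, 100); line[31, 11:90] <- 1L
  poly <- connect_cej(line)
  expect_true(all(poly$y == 30L))
  expect_identical(poly$x, 10:89)
  expect_true(all(diff(poly$x) == 1L))

  gapped <- line; gapped[31, 41:45] <- 0L
  poly2 <- connect_cej(gapped, window = 8)
  expect_identical(range(poly2$x), c(10L, 89L))
  expect_true(all(abs(diff(poly2$y)) <= 1))  # 8-connected

  expect_error(connect_cej(matrix(0L, 8, 8)), "no CEJ pixels")

  # a gap longer than gap_factor * window splits; longest segment kept
  split <- matrix(0L, 64, 200)
  split[31, 6:60] <- 1L; split[35, 120:195] <- 1L
  expect_warning(poly3 <- connect_cej(split, window = 8), "keeping longest")
  expect_true(min(poly3$x) >= 119)

  # per-column agreement with the mask centroid for wavy lines
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(0L, 64, 80)
    y0 <- sample(20:40, 1)
    ys <- round(y0 + 3 * sin(seq(0, 2 * pi, length.out = 80) + runif(1, 0, 6)))
    m[cbind(ys + 1, 1:80)] <- 1L
    p <- connect_cej(m)
    expect_gte(nrow(p), 80L)
    for (xx in c(0L, 39L, 79L)) {
      expect_lte(abs(p$y[p$x == xx] - ys[xx + 1]), 2)
    }
  }
})

test_that("bitewing CEJ masks split into an upper and a lower polyline", {
  m <- matrix(0L, 128, 100)
  m[41, 11:90] <- 1L; m[81, 11:90] <- 1L
  pair <- connect_cej_pair(m)
  expect_true(all(pair$upper$y == 40L))
  expect_true(all(pair$lower$y == 80L))
})
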