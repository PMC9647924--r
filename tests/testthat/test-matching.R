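test_that("match_score: self-match is 1, photometric inversion is -1 at equal size", {
  set.seed(3)
  p <- matrix(runif(30 * 20), 30, 20)
  expect_equal(match_score(p, p, 1)$score, 1, tolerance = 1e-8)
  expect_equal(match_score(1 - p, p, 1)$score, -1, tolerance = 1e-8)
})

test_that("match_score is invariant to affine intensity changes", {
  set.seed(4)
  p <- matrix(runif(24 * 16), 24, 16)
  q <- matrix(runif(30 * 22), 30, 22)
  base <- match_score(p, q, 1)$score
  expect_equal(match_score(clamp_test(0.5 * p + 0.2), q, 1)$score, base,
               tolerance = 1e-8)
  expect_equal(match_score(p, clamp_test(0.8 * q + 0.1), 1)$score, base,
               tolerance = 1e-8)
})

test_that("a shrunken copy attains its best score at the reciprocal scale", {
  g <- generate_tooth_glyph(16, 1.0, seed = 2)
  entry <- g$patch
  shrunk <- toothchart:::resize_gray(entry, nrow(entry) * 0.8, ncol(entry) * 0.8)
  scales <- seq(0.5, 1.5, by = 0.1)
  scores <- vapply(scales, function(s) match_score(shrunk, entry, s)$score, 0)
  best <- scales[which.max(scores)]
  # 1/0.8 = 1.25 sits between grid points 1.2 and 1.3
  expect_true(best %in% c(1.2, 1.3))
})

test_that("degenerate constant patches score 0 with a warning", {
  flat <- matrix(0.5, 10, 10)
  p <- matrix(runif(100), 10, 10)
  expect_warning(s <- match_score(flat, p, 1)$score, "degenerate")
  expect_equal(s, 0)
})

test_that("sliding max-correlation equals brute-force exhaustive shifts", {
  set.seed(9)
  for (rep in 1:50) {
    th <- sample(2:12, 1); tw <- sample(2:12, 1)
    img <- matrix(runif(16 * 16), 16, 16)
    tmpl <- matrix(runif(th * tw), th, tw)
    expect_equal(toothchart:::cpp_zncc_best(tmpl, img), zncc_brute(tmpl, img),
                 tolerance = 1e-10)
  }
})

test_that("assign_number votes correctly and honours k", {
  case <- tc_case(seed = 7)
  repo <- build_repository(list(list(image = case$panoramic$image,
                                     annotations = case$panoramic$teeth,
                                     source_id = "pan7")))
  idx24 <- which(vapply(repo$entries, `[[`, 0L, "fdi") == 24L)
  crop <- repo$entries[[idx24]]$crop
  a <- assign_number(crop, repo)
  expect_s3_class(a, "fdi_assignment")
  expect_equal(a$fdi, 24L)
  expect_equal(sum(a$votes), min(10L, length(repo$entries)))
  expect_equal(nrow(a$top_scores), 10L)
  expect_true(all(diff(a$top_scores$score) <= 0))

  a1 <- assign_number(crop, repo, k = 1)
  expect_equal(a1$fdi, a1$top_scores$fdi[1])
  expect_equal(sum(a1$votes), 1L)

  expect_error(assign_number(crop, toothchart:::new_repository(list())),
               "empty repository")
})

test_that("assignment is invariant to repository permutation and monotone in correct entries", {
  case <- tc_case(seed = 7)
  repo <- build_repository(list(list(image = case$panoramic$image,
                                     annotations = case$panoramic$teeth,
                                     source_id = "pan7")))
  crop <- repo$entries[[5]]$crop
  truth <- repo$entries[[5]]$fdi
  a <- assign_number(crop, repo)
  set.seed(1)
  perm <- toothchart:::new_repository(sample(repo$entries))
  ap <- assign_number(crop, perm)
  expect_equal(ap$fdi, a$fdi)

  # adding more correct-label entries never decreases the correct vote count
  v0 <- sum(a$top_scores$fdi == truth)
  more <- toothchart:::new_repository(
    c(repo$entries, repo$entries[vapply(repo$entries, `[[`, 0L, "fdi") == truth]))
  am <- assign_number(crop, more)
  expect_gte(sum(am$top_scores$fdi == truth), v0)
  expect_equal(am$fdi, truth)
})

test_that("panoramic-view labeling reproduces gold arch order, with and without gaps", {
  case <- tc_case(seed = 7)
  b <- boxes_from_panoramic(case$panoramic$tooth_mask)
  lb <- toothchart:::label_panoramic_boxes(b)
  gold <- case$panoramic$teeth
  key <- merge(lb[, c("x0", "y0", "fdi")], gold[, c("x0", "y0", "fdi")],
               by = c("x0", "y0"))
  expect_equal(nrow(key), 32L)
  expect_true(all(key$fdi.x == key$fdi.y))

  miss <- tc_case(seed = 6, missing_fdi = 36)
  bm <- boxes_from_panoramic(miss$panoramic$tooth_mask)
  lbm <- toothchart:::label_panoramic_boxes(bm)
  goldm <- miss$panoramic$teeth
  keym <- merge(lbm[, c("x0", "y0", "fdi")], goldm[, c("x0", "y0", "fdi")],
                by = c("x0", "y0"))
  expect_equal(nrow(keym), 31L)
  expect_true(all(keym$fdi.x == keym$fdi.y))

  expect_error(toothchart:::label_panoramic_boxes(
    data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0),
               y1 = integer(0))), "zero extracted teeth")
})

test_that("matching intraoral crops against the patient panoramic numbers them correctly", {
  case <- tc_case(seed = 7)
  pa <- case$periapicals[[4]]   # incisor block, four teeth
  cej <- connect_cej(pa$cej_mask)
  bx <- boxes_from_intraoral(pa$tooth_mask, cej, pa$position)
  crops <- crop_teeth(pa$image, bx, pa$id)
  asn <- assign_numbers_via_panoramic(crops, case$panoramic$image,
                                      case$panoramic$tooth_mask)
  expect_equal(vapply(asn, `[[`, 0L, "fdi"), pa$teeth$fdi)
  expect_true(all(vapply(asn, `[[`, "", "mode") == "panoramic_view"))
})
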