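test_that("dsc and ji match hand counts and handle empty masks", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  expect_equal(dsc(a, b), 1)
  expect_equal(ji(a, b), 1)
  a[1, 1:4] <- 1L                    # |A| = 4
  b[1, 3:4] <- 1L; b[2, 1:2] <- 1L   # |B| = 4, overlap 2
  expect_equal(dsc(a, b), 0.5)
  expect_equal(ji(a, b), 1 / 3)
  expect_equal(dsc(a, a), 1)
  expect_equal(ji(a, a), 1)
  disj <- matrix(0L, 4, 4); disj[4, ] <- 1L
  expect_equal(dsc(a, disj), 0)
  expect_equal(ji(a, disj), 0)
  expect_error(dsc(a, matrix(0L, 3, 3)), "dimensions differ")
})

test_that("DSC = 2 JI / (1 + JI) on random mask pairs", {
  set.seed(13)
  for (rep in 1:200) {
    a <- matrix(as.integer(runif(100) < 0.4), 10, 10)
    b <- matrix(as.integer(runif(100) < 0.4), 10, 10)
    j <- ji(a, b)
    expect_equal(dsc(a, b), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("box_ji equals ji of the rasterized boxes", {
  b1 <- data.frame(x0 = 0, y0 = 0, x1 = 4, y1 = 4)
  expect_equal(box_ji(b1, b1), 1)
  b2 <- data.frame(x0 = 6, y0 = 6, x1 = 9, y1 = 9)
  expect_equal(box_ji(b1, b2), 0)
  set.seed(17)
  for (rep in 1:200) {
    a <- random_box(20, 20); b <- random_box(20, 20)
    expect_equal(box_ji(a, b),
                 ji(rasterize_box(a, 20, 20), rasterize_box(b, 20, 20)),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_detection applies the JI > 0.7 successful-match rule", {
  gold <- data.frame(x0 = c(0, 10, 20, 30, 40), y0 = 0,
                     x1 = c(5, 15, 25, 35, 45), y1 = 10,
                     fdi = c(11L, 12L, 13L, 14L, 15L))
  # perfect predictions
  ev <- evaluate_detection(gold, gold)
  expect_equal(ev$detection_precision, 1)
  expect_equal(ev$detection_recall, 1)
  expect_equal(ev$numbering_precision, 1)
  expect_equal(ev$numbering_recall, 1)

  # 4 predictions, 2 successful (exact boxes), 2 with correct numbers
  pred <- data.frame(x0 = c(0, 10, 100, 120), y0 = c(0, 0, 0, 0),
                     x1 = c(5, 15, 105, 125), y1 = c(10, 10, 10, 10),
                     fdi = c(11L, 12L, 13L, 14L))
  ev2 <- evaluate_detection(pred, gold)
  expect_equal(ev2$n_successful, 2L)
  expect_equal(ev2$n_true_number, 2L)
  expect_equal(ev2$detection_precision, 0.5)
  expect_equal(ev2$detection_recall, 0.4)
  expect_equal(ev2$numbering_precision, 0.5)
  expect_equal(ev2$numbering_recall, 0.4)

  # zero predictions: recall 0, precision undefined (NA, not 0)
  none <- gold[0, ]
  ev3 <- evaluate_detection(none, gold)
  expect_equal(ev3$detection_recall, 0)
  expect_true(is.na(ev3$detection_precision))

  # JI exactly at the threshold is NOT a successful match (strict rule)
  g1 <- data.frame(x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  p1 <- data.frame(x0 = 0, y0 = 0, x1 = 10, y1 = 7)
  expect_equal(box_ji(p1, g1), 0.7)
  expect_equal(evaluate_detection(p1, g1)$n_successful, 0L)
})

test_that("detection evaluation invariants hold on random inputs", {
  set.seed(23)
  for (rep in 1:50) {
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    mk <- function(n) {
      if (n == 0) return(data.frame(x0 = integer(0), y0 = integer(0),
                                    x1 = integer(0), y1 = integer(0),
                                    fdi = integer(0)))
      do.call(rbind, lapply(seq_len(n), function(i)
        cbind(random_box(30, 30), fdi = sample(c(11:18), 1))))
    }
    ev <- evaluate_detection(mk(np), mk(ng))
    expect_lte(ev$n_successful, min(np, ng))
    expect_lte(ev$n_true_number, ev$n_successful)
    for (r in c(ev$detection_precision, ev$detection_recall,
                ev$numbering_precision, ev$numbering_recall))
      expect_true(is.na(r) || (r >= 0 && r <= 1))
  }
})

test_that("numbering and position accuracy are exact fractions", {
  expect_equal(numbering_accuracy(c(11, 12, 13), c(11, 12, 13)), 1)
  expect_equal(numbering_accuracy(c(11, 12), c(21, 22)), 0)
  expect_equal(numbering_accuracy(c(11, 12, 13, 14), c(11, 12, 13, 24)), 0.75)
  expect_error(numbering_accuracy(integer(0), integer(0)), "empty")
  expect_equal(position_accuracy(c("maxilla", "mandible"),
                                 c("maxilla", "mandible")), 1)
  expect_equal(position_accuracy(c("maxilla", "mandible"),
                                 c("maxilla", "bitewing")), 0.5)
  expect_error(position_accuracy(character(0), character(0)), "empty")
})

test_that("sensitivity and specificity reduce one-vs-rest correctly", {
  d <- diag(c(5, 7, 9)); dimnames(d) <- list(1:3, 1:3)
  for (k in 1:3) {
    ss <- sensitivity_specificity(d, as.character(k))
    expect_equal(unname(ss["sensitivity"]), 1)
    expect_equal(unname(ss["specificity"]), 1)
  }
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  ss <- sensitivity_specificity(cm, "pos")
  expect_equal(unname(ss["sensitivity"]), 0.8)
  expect_equal(unname(ss["specificity"]), 0.9)

  zero <- matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(sensitivity_specificity(zero, "a")["sensitivity"]))
  expect_error(sensitivity_specificity(cm, "nope"), "unknown class")
})
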