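# Evaluation metrics: Dice and Jaccard for masks, closed-form box IoU, the
# JI > 0.7 successful-match rule with detection/numbering precision and
# recall, numbering and position accuracy, and one-vs-rest sensitivity /
# specificity from a confusion matrix. Ratios with a zero denominator are
# reported as NA ("undefined"), deliberately distinct from 0.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary matrices of equal dimensions.
#' @return Value in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Jaccard index of two binary masks
#'
#' `|A n B| / |A u B|`; defined as 1 when both masks are empty.
#'
#' @inheritParams dsc
#' @return Value in `[0, 1]`.
#' @export
ji <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ")
  un <- sum(a != 0 | b != 0)
  if (un == 0) return(1)
  sum(a != 0 & b != 0) / un
}

#' Jaccard index of two axis-aligned boxes
#'
#' Closed-form intersection-over-union of half-open rectangles; equals
#' [ji()] of the rasterized boxes on any grid containing both.
#'
#' @param a,b One-row data frames (or lists) with `x0, y0, x1, y1`.
#' @return Value in `[0, 1]`.
#' @export
box_ji <- function(a, b) {
  iw <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  ih <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- iw * ih
  area <- function(z) (z$x1 - z$x0) * (z$y1 - z$y0)
  un <- area(a) + area(b) - inter
  if (un <= 0) return(1)
  inter / un
}

#' Evaluate detected boxes and numbers against gold standard
#'
#' Predictions and gold boxes are paired greedily by descending box Jaccard
#' index, one-to-one; pairs with JI strictly above `threshold` are
#' successful matches. Among successful matches, agreeing FDI numbers count
#' as true-positive numbering. Detection precision = successful / detected,
#' detection recall = successful / gold, numbering precision = true-number /
#' detected, numbering recall = true-number / gold.
#'
#' @param pred,gold Data frames of boxes (`x0, y0, x1, y1`), optionally with
#'   an `fdi` column for the numbering metrics.
#' @param threshold Successful-match JI cut in `(0, 1)`, default 0.7.
#' @return List of class `detection_eval`: counts `n_detected`, `n_gold`,
#'   `n_successful`, `n_true_number` and the four ratios (NA when their
#'   denominator is zero).
#' @export
evaluate_detection <- function(pred, gold, threshold = 0.7) {
  stopifnot(threshold > 0, threshold < 1)
  np <- NROW(pred); ng <- NROW(gold)
  pairs <- NULL
  if (np > 0 && ng > 0) {
    all_ji <- expand.grid(p = seq_len(np), g = seq_len(ng))
    all_ji$ji <- mapply(function(i, j) box_ji(pred[i, ], gold[j, ]),
                        all_ji$p, all_ji$g)
    all_ji <- all_ji[order(-all_ji$ji), ]
    used_p <- logical(np); used_g <- logical(ng)
    for (r in seq_len(nrow(all_ji))) {
      i <- all_ji$p[r]; j <- all_ji$g[r]
      if (!used_p[i] && !used_g[j] && all_ji$ji[r] > threshold) {
        used_p[i] <- TRUE; used_g[j] <- TRUE
        pairs <- rbind(pairs, data.frame(p = i, g = j, ji = all_ji$ji[r]))
      }
    }
  }
  n_succ <- NROW(pairs)
  n_true <- if (n_succ > 0 && !is.null(pred$fdi) && !is.null(gold$fdi))
    sum(pred$fdi[pairs$p] == gold$fdi[pairs$g]) else
      if (is.null(pred$fdi) || is.null(gold$fdi)) NA_integer_ else 0L
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    n_detected = np, n_gold = ng, n_successful = n_succ,
    n_true_number = n_true,
    detection_precision = ratio(n_succ, np),
    detection_recall = ratio(n_succ, ng),
    numbering_precision = if (is.na(n_true)) NA_real_ else ratio(n_true, np),
    numbering_recall = if (is.na(n_true)) NA_real_ else ratio(n_true, ng),
    pairs = pairs), class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(paste0("detection_eval: %d detected / %d gold, %d successful ",
                     "(DP %.3f, DR %.3f, NP %.3f, NR %.3f)\n"),
              x$n_detected, x$n_gold, x$n_successful,
              x$detection_precision, x$detection_recall,
              x$numbering_precision, x$numbering_recall))
  invisible(x)
}

#' Tooth numbering accuracy
#'
#' Fraction of teeth whose predicted number equals the true number.
#'
#' @param truth,pred Equal-length vectors of FDI numbers.
#' @return Value in `[0, 1]`.
#' @export
numbering_accuracy <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0L) stop("empty record list")
  mean(truth == pred)
}

#' Radiograph position accuracy
#'
#' Fraction of radiographs whose predicted position equals the true one.
#'
#' @param truth,pred Equal-length vectors of positions.
#' @return Value in `[0, 1]`.
#' @export
position_accuracy <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0L) stop("empty record list")
  mean(truth == pred)
}

#' One-vs-rest sensitivity and specificity from a confusion matrix
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP). A zero
#' denominator (e.g. a class with no support) yields NA.
#'
#' @param cm K x K matrix of counts; rows are true classes, columns
#'   predicted, with matching dimnames.
#' @param positive_class Row/column name (or index) treated as positive.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(cm, positive_class) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  if (is.character(positive_class)) {
    if (!positive_class %in% rownames(cm)) stop("unknown class: ", positive_class)
    k <- match(positive_class, rownames(cm))
  } else {
    if (positive_class < 1 || positive_class > nrow(cm))
      stop("unknown class: ", positive_class)
    k <- positive_class
  }
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}
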