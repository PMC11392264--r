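# Pixel-level evaluation: confusion counts, the four standard mask metrics
# (Dice similarity coefficient, precision, recall, intersection over
# union) and pooled precision-recall sweeps.

#' Pixel confusion counts
#'
#' Binarises the probability map at `p >= threshold` and counts
#' agreements/disagreements against the binary reference.
#'
#' @param p numeric array of predicted probabilities in `[0, 1]`.
#' @param q numeric array of binary labels, same shape.
#' @param threshold binarisation threshold in `(0, 1)` (inclusive `>=`).
#' @return a `confusion_counts` list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(p, q, threshold = 0.5) {
  if (length(p) != length(q)) {
    stop("confusion_counts: shapes differ (", length(p), " vs ", length(q), ")")
  }
  stopifnot(threshold > 0, threshold < 1)
  pb <- p >= threshold
  qb <- q >= 0.5
  structure(list(
    tp = sum(pb & qb), fp = sum(pb & !qb),
    fn = sum(!pb & qb), tn = sum(!pb & !qb)
  ), class = "confusion_counts")
}

.safe_ratio <- function(num, den, both_empty) {
  if (den == 0) {
    return(if (both_empty) 1 else 0)
  }
  num / den
}

#' Mask metrics from confusion counts
#'
#' DSC = 2TP/(2TP+FP+FN), precision = TP/(TP+FP), recall = TP/(TP+FN),
#' IoU = TP/(TP+FP+FN). Any 0/0 is defined as 1 when both the reference
#' mask and the prediction are empty (a correctly predicted empty image),
#' else 0.
#'
#' @param counts a [confusion_counts()] result (or a list with tp/fp/fn/tn).
#' @return a named numeric vector with `dsc`, `precision`, `recall`, `iou`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  both_empty <- (tp + fp == 0) && (tp + fn == 0)
  c(
    dsc = .safe_ratio(2 * tp, 2 * tp + fp + fn, both_empty),
    precision = .safe_ratio(tp, tp + fp, both_empty),
    recall = .safe_ratio(tp, tp + fn, both_empty),
    iou = .safe_ratio(tp, tp + fp + fn, both_empty)
  )
}

#' Evaluate one prediction/reference pair
#' @inheritParams confusion_counts
#' @return a named numeric vector with `dsc`, `precision`, `recall`, `iou`.
#' @export
evaluate_pair <- function(p, q, threshold = 0.5) {
  metrics_from_counts(confusion_counts(p, q, threshold))
}

#' Evaluate a set of predictions
#'
#' @param p_list list of probability arrays.
#' @param q_list list of binary reference arrays, same lengths and shapes.
#' @param threshold binarisation threshold.
#' @param aggregate `"per_image"` (default: metrics computed per image and
#'   averaged, the dominant convention for the polyp benchmarks) or
#'   `"pooled"` (confusion counts pooled over all images first).
#' @param ids optional identifiers for the per-image rows.
#' @return a data.frame with one row per image plus a final `summary` row
#'   holding the aggregate.
#' @export
evaluate_dataset <- function(p_list, q_list, threshold = 0.5,
                             aggregate = c("per_image", "pooled"),
                             ids = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(p_list) == length(q_list), length(p_list) > 0)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(p_list))
  counts <- Map(confusion_counts, p_list, q_list, MoreArgs = list(threshold = threshold))
  rows <- t(vapply(counts, metrics_from_counts, numeric(4)))
  summary_row <- if (aggregate == "per_image") {
    colMeans(rows)
  } else {
    pooled <- list(
      tp = sum(vapply(counts, `[[`, numeric(1), "tp")),
      fp = sum(vapply(counts, `[[`, numeric(1), "fp")),
      fn = sum(vapply(counts, `[[`, numeric(1), "fn")),
      tn = sum(vapply(counts, `[[`, numeric(1), "tn"))
    )
    metrics_from_counts(pooled)
  }
  out <- data.frame(id = c(ids, "summary"),
                    rbind(rows, summary_row), row.names = NULL)
  names(out) <- c("id", "dsc", "precision", "recall", "iou")
  out
}

#' Pooled precision-recall sweep
#'
#' For each threshold, pools confusion counts over the whole dataset and
#' reports the operating point.
#'
#' @param p_list list of probability arrays.
#' @param q_list list of binary reference arrays.
#' @param thresholds strictly increasing vector in `(0, 1)`.
#' @return a data.frame with columns `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(p_list, q_list,
                     thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(p_list) == length(q_list))
  if (length(p_list) == 0) stop("pr_curve: empty dataset")
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("pr_curve: thresholds must be strictly increasing in (0, 1)")
  }
  pts <- t(vapply(thresholds, function(th) {
    tp <- fp <- fn <- 0
    for (i in seq_along(p_list)) {
      cc <- confusion_counts(p_list[[i]], q_list[[i]], th)
      tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
    }
    both_empty <- (tp + fp == 0) && (tp + fn == 0)
    c(precision = .safe_ratio(tp, tp + fp, both_empty),
      recall = .safe_ratio(tp, tp + fn, both_empty))
  }, numeric(2)))
  data.frame(threshold = thresholds, pts)
}
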