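#' Volume error
#'
#' Signed relative volume difference `VE = 2 (S - G) / (S + G)` between the
#' predicted-positive count `S` and the ground-truth-positive count `G`,
#' in `[-2, 2]`; the reported percentage is `|VE| * 100`. Antisymmetric in
#' its arguments. Both counts zero is defined as 0 with a warning.
#'
#' @param S predicted positive-pixel count (or a [seg_mask]).
#' @param G truth positive-pixel count (or a [seg_mask]).
#' @return list with `fraction` (signed) and `percent` (absolute).
#' @export
volume_error <- function(S, G) {
  if (inherits(S, "seg_mask") || is.matrix(S)) S <- sum(as_mask_pixels(S))
  if (inherits(G, "seg_mask") || is.matrix(G)) G <- sum(as_mask_pixels(G))
  if (S < 0 || G < 0) stop_input("counts must be non-negative")
  if (S + G == 0) {
    warning("both masks empty: volume error defined as 0", call. = FALSE)
    return(list(fraction = 0, percent = 0))
  }
  ve <- 2 * (S - G) / (S + G)
  list(fraction = ve, percent = abs(ve) * 100)
}

mask_pair <- function(S, G) {
  s <- as_mask_pixels(S)
  g <- as_mask_pixels(G)
  if (!all(dim(s) == dim(g)))
    stop_input("masks must have the same shape")
  list(s = s, g = g)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |G intersect S| / (|G| + |S|)`, in `[0, 1]`; 1 means the
#' segmentation reproduces the gold mask exactly. Two empty masks are in
#' perfect agreement and score 1 (with a warning).
#'
#' @param S,G [seg_mask]s or binary matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(S, G) {
  p <- mask_pair(S, G)
  denom <- sum(p$s) + sum(p$g)
  if (denom == 0) {
    warning("both masks empty: DSC defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(p$s & p$g) / denom
}

#' Jaccard similarity score
#'
#' `JSS = |G intersect S| / |G union S|`, in `[0, 1]`; related to Dice by
#' `DSC = 2 JSS / (1 + JSS)` and never exceeds it.
#'
#' @inheritParams dice
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(S, G) {
  p <- mask_pair(S, G)
  u <- sum(p$s | p$g)
  if (u == 0) {
    warning("both masks empty: JSS defined as 1", call. = FALSE)
    return(1)
  }
  sum(p$s & p$g) / u
}

#' Classification accuracy percentage
#'
#' `Y = s / m * 100` for `s` correct out of `m` evaluated.
#'
#' @param s correct count, `0 <= s <= m`. @param m total count, `> 0`.
#' @return percentage in `[0, 100]`.
#' @export
accuracy <- function(s, m) {
  if (m <= 0) stop_input("total count m must be > 0")
  if (s < 0 || s > m) stop_input("correct count must satisfy 0 <= s <= m")
  s / m * 100
}

#' Confusion counts
#'
#' @param T_plus,T_minus,F_plus,F_minus true/false positive/negative counts.
#' @return validated `confusion_counts` list.
#' @export
confusion_counts <- function(T_plus, T_minus, F_plus, F_minus) {
  v <- c(T_plus, T_minus, F_plus, F_minus)
  if (any(v < 0)) stop_input("confusion counts must be non-negative")
  structure(list(T_plus = T_plus, T_minus = T_minus, F_plus = F_plus,
                 F_minus = F_minus), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param pred,truth 0/1 label vectors of equal length.
#' @export
confusion_from_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) stop_input("label vectors must align")
  confusion_counts(sum(pred == 1 & truth == 1), sum(pred == 0 & truth == 0),
                   sum(pred == 1 & truth == 0), sum(pred == 0 & truth == 1))
}

#' F1 score
#'
#' `F1 = T+ / (T+ + (F+ + F-) / 2)`, algebraically the harmonic mean of
#' precision and recall. A zero denominator (no positives anywhere) is
#' defined as 0 with a warning.
#'
#' @param c a [confusion_counts].
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(c) {
  denom <- c$T_plus + 0.5 * (c$F_plus + c$F_minus)
  if (denom == 0) {
    warning("no positives in prediction or truth: F1 defined as 0",
            call. = FALSE)
    return(0)
  }
  c$T_plus / denom
}

#' Root-mean-square error between two value lists
#'
#' @param predicted,truth equal-length numeric vectors.
#' @return `sqrt(mean((predicted - truth)^2))`; 0 iff identical.
#' @export
rmse <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) < 1)
    stop_input("inputs must be equal-length, non-empty")
  sqrt(mean((predicted - truth)^2))
}

#' Left-right ventilation imbalance coefficient
#'
#' `(L - R) / (L + R)` in `[-1, +1]`: +1 when only the left lung is
#' ventilated (`R = 0`), -1 when only the right. A standalone physiological
#' utility, not connected to the segmentation pipeline.
#'
#' @param left,right non-negative tidal ventilation values, not both zero.
#' @return coefficient in `[-1, 1]`.
#' @export
lr_imbalance <- function(left, right) {
  if (left < 0 || right < 0) stop_input("ventilation values must be >= 0")
  if (left + right == 0) stop_input("left + right must be > 0")
  (left - right) / (left + right)
}

#' k-fold cross-validation plan
#'
#' Seeded shuffle followed by a balanced partition: folds are disjoint,
#' cover every index, and differ in size by at most one.
#'
#' @param n number of items. @param k number of folds, `k <= n`.
#' @param seed shuffle seed.
#' @return `fold_plan` with `folds` (list of index vectors), `k`, `seed`.
#' @export
kfold_plan <- function(n, k, seed = 1L) {
  if (k > n) stop_input("k must not exceed n")
  if (k < 1) stop_input("k must be >= 1")
  ord <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)  # sizes differ by <= 1
  folds <- split(ord, fold_of)
  names(folds) <- NULL
  structure(list(folds = folds, k = as.integer(k), n = as.integer(n),
                 seed = as.integer(seed)), class = "fold_plan")
}

#' Evaluate a segmentation run
#'
#' Per-item volume error, Dice and Jaccard against ground truth, aggregated
#' as mean +/- population standard deviation; optional classification
#' labels add accuracy and F1. Wall-clock per-item timing is recorded for
#' information only.
#'
#' @param pred list of predicted [seg_mask]s (or binary matrices).
#' @param truth list of ground-truth masks, same length and order.
#' @param pred_labels,true_labels optional 0/1 classification labels.
#' @return a `metrics_report` list: `per_item` data.frame, `summary`
#'   data.frame (mean, sd per metric), optional `classification`.
#' @export
evaluate_run <- function(pred, truth, pred_labels = NULL, true_labels = NULL) {
  if (length(pred) != length(truth))
    stop_input("pred and truth sets misaligned: ", length(pred), " vs ",
               length(truth), " items")
  if (length(pred) == 0) stop_input("nothing to evaluate")
  rows <- lapply(seq_along(pred), function(i) {
    t0 <- proc.time()[["elapsed"]]
    ve <- volume_error(pred[[i]], truth[[i]])
    d <- dice(pred[[i]], truth[[i]])
    j <- jaccard(pred[[i]], truth[[i]])
    data.frame(item = i, ve_percent = ve$percent, ve_fraction = ve$fraction,
               dsc = d, jss = j,
               seconds = proc.time()[["elapsed"]] - t0)
  })
  per_item <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summarize <- function(col) c(mean = mean(per_item[[col]]),
                               sd = pop_sd(per_item[[col]]))
  summary <- data.frame(
    metric = c("ve_percent", "dsc", "jss", "seconds"),
    mean = c(summarize("ve_percent")[1], summarize("dsc")[1],
             summarize("jss")[1], summarize("seconds")[1]),
    sd = c(summarize("ve_percent")[2], summarize("dsc")[2],
           summarize("jss")[2], summarize("seconds")[2]))
  report <- list(per_item = per_item, summary = summary)
  if (!is.null(pred_labels) && !is.null(true_labels)) {
    cc <- confusion_from_labels(pred_labels, true_labels)
    report$classification <- list(
      confusion = cc,
      accuracy_percent = accuracy(cc$T_plus + cc$T_minus,
                                  length(true_labels)),
      f1 = f1_score(cc))
  }
  structure(report, class = "metrics_report")
}

#' Write a metrics report
#'
#' JSON for the full report, CSV mirroring the mean +/- sd table layout.
#'
#' @param report a `metrics_report`.
#' @param json_path,csv_path output paths (either may be NULL).
#' @return invisible `report`.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    cls <- report$classification
    if (!is.null(cls)) cls$confusion <- unclass(cls$confusion)
    jsonlite::write_json(
      list(per_item = report$per_item, summary = report$summary,
           classification = cls),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    tab <- data.frame(
      metric = report$summary$metric,
      mean_sd = sprintf("%.4f ± %.4f", report$summary$mean,
                        report$summary$sd))
    write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(report)
}
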