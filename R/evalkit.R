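# Detection matching and metrics: per-class TP/FP/FN, class-averaged
# precision and recall, F1, and average precision by all-points
# precision-envelope integration (mAP averages AP over classes).

#' Intersection-over-union of two boxes
#'
#' Boxes use the package's normalised dialect `c(cx, cy, w, h)` (centre and
#' extents).  Degenerate (zero-area) boxes yield 0 with a warning.
#'
#' @param a,b Numeric length-4 vectors `c(cx, cy, w, h)`.
#' @return Overlap ratio in `[0, 1]`.
#' @examples
#' iou(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2))  # 1
#' @export
iou <- function(a, b) {
  if (a[3] * a[4] <= 0 || b[3] * b[4] <= 0) {
    warning("iou: zero-area box; returning 0")
    return(0)
  }
  iou_xyxy(cxcywh_to_xyxy(a), cxcywh_to_xyxy(b))
}

cxcywh_to_xyxy <- function(b) {
  c(b[1] - b[3] / 2, b[2] - b[4] / 2, b[1] + b[3] / 2, b[2] + b[4] / 2)
}

iou_xyxy <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  if (union <= 0) 0 else inter / union
}

# vectorised IoU of one xyxy box against a 4-column matrix of xyxy boxes
iou_one_many <- function(a, m) {
  iw <- pmax(0, pmin(a[3], m[, 3]) - pmax(a[1], m[, 1]))
  ih <- pmax(0, pmin(a[4], m[, 4]) - pmax(a[2], m[, 2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter
  ifelse(union <= 0, 0, inter / union)
}

#' Match predicted detections against ground truth
#'
#' Predictions are visited in order of descending confidence; each is a true
#' positive if its best-IoU unmatched same-class truth reaches
#' `iou_threshold` (that truth is then consumed), otherwise a false
#' positive.  Unmatched truths are false negatives.
#'
#' @param preds Data frame with columns `class`, `cx`, `cy`, `bw`, `bh`,
#'   `conf` (a `detection_set`, e.g. from [decode_predictions()]).
#' @param truths Data frame with columns `class`, `cx`, `cy`, `bw`, `bh`.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return A `match_result`: per-class `counts` (TP/FP/FN), the `ranked`
#'   data frame (class, conf, tp flag) for AP computation, `n_truth` per
#'   class, and matched pair IoUs.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  preds <- as.data.frame(preds)
  truths <- as.data.frame(truths)
  classes <- sort(unique(c(preds$class, truths$class)))
  if (nrow(preds) > 0) {
    ord <- order(-preds$conf)
    preds <- preds[ord, , drop = FALSE]
  }
  tmat <- if (nrow(truths) > 0)
    t(apply(truths[, c("cx", "cy", "bw", "bh")], 1, cxcywh_to_xyxy))
  else matrix(0, 0, 4)
  used <- rep(FALSE, nrow(truths))
  tp <- logical(nrow(preds))
  pair_iou <- numeric(0)
  for (i in seq_len(nrow(preds))) {
    cand <- which(!used & truths$class == preds$class[i])
    if (length(cand) == 0) next
    pb <- cxcywh_to_xyxy(as.numeric(preds[i, c("cx", "cy", "bw", "bh")]))
    ious <- iou_one_many(pb, tmat[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
      pair_iou <- c(pair_iou, ious[j])
    }
  }
  counts <- do.call(rbind, lapply(classes, function(cl) {
    pc <- preds$class == cl
    data.frame(class = cl,
               tp = sum(tp[pc]),
               fp = sum(!tp[pc]),
               fn = sum(truths$class == cl) - sum(tp[pc]))
  }))
  structure(list(counts = counts,
                 ranked = data.frame(class = preds$class, conf = preds$conf,
                                     tp = tp),
                 n_truth = stats::setNames(
                   vapply(classes, function(cl) sum(truths$class == cl), 0),
                   classes),
                 pair_iou = pair_iou),
            class = "match_result")
}

# all-points average precision from ranked (conf, tp) flags
ap_ranked <- function(conf, tp, n_truth) {
  if (n_truth == 0) return(0)
  if (length(conf) == 0) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope: running max from the right
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Precision, recall, F1, AP and mAP from match results
#'
#' Precision and recall are class-averaged:
#' `P = (1/n) * sum_i TP_i / (TP_i + FP_i)` and
#' `R = (1/n) * sum_i TP_i / (TP_i + FN_i)`; `F1 = 2PR/(P+R)` (0 when
#' `P + R = 0`).  AP integrates the all-points precision envelope over
#' recall per class; mAP averages AP over classes.  Zero denominators
#' define the metric as 0 and are flagged in the result.
#'
#' @param matches A `match_result` or a list of them (e.g. one per image);
#'   ranked detections are pooled across the list for AP.
#' @return A `metrics_report` list: `P`, `R`, `F1`, `mAP`, per-class
#'   `per_class` data frame, and `flags` noting degenerate denominators.
#' @export
metrics <- function(matches) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  counts <- do.call(rbind, lapply(matches, function(m) m$counts))
  agg <- stats::aggregate(counts[, c("tp", "fp", "fn")],
                          by = list(class = counts$class), FUN = sum)
  ranked <- do.call(rbind, lapply(matches, function(m) m$ranked))
  n_truth <- Reduce(`+`, lapply(matches, function(m) {
    v <- stats::setNames(rep(0, nrow(agg)), agg$class)
    v[names(m$n_truth)] <- m$n_truth
    v
  }))
  flags <- character(0)
  per <- lapply(seq_len(nrow(agg)), function(r) {
    tp <- agg$tp[r]; fp <- agg$fp[r]; fn <- agg$fn[r]
    p <- if (tp + fp > 0) tp / (tp + fp) else {
      flags <<- c(flags, sprintf("class %s: no predictions, P := 0",
                                 agg$class[r]))
      0
    }
    rc <- if (tp + fn > 0) tp / (tp + fn) else {
      flags <<- c(flags, sprintf("class %s: no ground truth, R := 0",
                                 agg$class[r]))
      0
    }
    sel <- ranked$class == agg$class[r]
    ap <- ap_ranked(ranked$conf[sel], ranked$tp[sel],
                    n_truth[as.character(agg$class[r])])
    data.frame(class = agg$class[r], tp = tp, fp = fp, fn = fn,
               precision = p, recall = rc, ap = ap)
  })
  per <- do.call(rbind, per)
  P <- mean(per$precision); R <- mean(per$recall)
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(P = P, R = R, F1 = F1, mAP = mean(per$ap),
                 per_class = per, flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  mAP = %.4f\n",
              x$P, x$R, x$F1, x$mAP))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Precision/recall/F1 from a binary confusion table
#'
#' Utility for video-level or image-level binary confusion counts.
#'
#' @param tp,fp,fn,tn Confusion counts (`tn` optional, for accuracy).
#' @return List with `precision`, `recall`, `f1` and (if `tn` given)
#'   `accuracy`.
#' @examples
#' confusion_metrics(tp = 395, fp = 28, fn = 35, tn = 427)
#' @export
confusion_metrics <- function(tp, fp, fn, tn = NULL) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  out <- list(precision = p, recall = r,
              f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
  if (!is.null(tn))
    out$accuracy <- (tp + tn) / (tp + fp + fn + tn)
  out
}
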