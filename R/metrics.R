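#' Match detections against ground truth at an IoU threshold
#'
#' Per class, predictions sorted by confidence (descending) greedily claim
#' the highest-IoU unmatched ground-truth box with IoU at or above the
#' threshold; unclaimed predictions count as false positives, unclaimed
#' truths as false negatives.
#'
#' @param preds detection box table (`cx, cy, w, h, cls, conf`).
#' @param gts ground-truth box table (`cx, cy, w, h, cls`).
#' @param iouThresh matching IoU threshold in (0, 1); default 0.5.
#' @return list with per-class `tp`, `fp`, `fn` (named vectors over classes
#'   present) and a `matches` data.frame (pred row, gt row, IoU, class).
#' @export
matchDetections <- function(preds, gts, iouThresh = 0.5) {
  stopifnot(iouThresh > 0, iouThresh < 1)
  classes <- POD_CLASSES
  tp <- fp <- fn <- setNames(integer(length(classes)), classes)
  matches <- list()
  for (cl in classes) {
    p <- preds[preds$cls == cl, , drop = FALSE]
    g <- gts[gts$cls == cl, , drop = FALSE]
    if (nrow(p)) p <- p[order(p$conf, decreasing = TRUE), , drop = FALSE]
    used <- logical(nrow(g))
    for (i in seq_len(nrow(p))) {
      if (!nrow(g)) { fp[cl] <- fp[cl] + 1L; next }
      ious <- iouMatrix(p[i, , drop = FALSE], g)[1, ]
      ious[used] <- -1
      k <- which.max(ious)
      if (length(k) && ious[k] >= iouThresh) {
        used[k] <- TRUE; tp[cl] <- tp[cl] + 1L
        matches[[length(matches) + 1L]] <-
          data.frame(pred = i, gt = k, iou = ious[k], cls = cl)
      } else fp[cl] <- fp[cl] + 1L
    }
    fn[cl] <- sum(!used)
  }
  list(tp = tp, fp = fp, fn = fn,
       matches = if (length(matches)) do.call(rbind, matches) else
         data.frame(pred = integer(), gt = integer(), iou = numeric(),
                    cls = character()))
}

#' Detection precision and recall (percent)
#'
#' `precisionPct` is `100 * TP / (TP + FP)`; `recallPct` is
#' `100 * TP / (TP + FN)`.
#'
#' @param tp,fp,fn true-positive / false-positive / false-negative counts.
#' @export
precisionPct <- function(tp, fp) {
  if (any(tp + fp <= 0)) stop("precision undefined: no predictions")
  100 * tp / (tp + fp)
}

#' @rdname precisionPct
#' @export
recallPct <- function(tp, fn) {
  if (any(tp + fn <= 0)) stop("recall undefined: no ground truths")
  100 * tp / (tp + fn)
}

#' Average precision from scored match outcomes
#'
#' Area under the interpolated precision-recall curve for one class:
#' predictions (pooled over images) sorted by confidence, cumulative
#' precision/recall, monotone precision envelope, averaged at 101 evenly
#' spaced recall levels (`interpolation = "101point"`, the default) or
#' integrated over all recall change points (`"allpoint"`).
#'
#' @param conf confidence of each prediction.
#' @param isTp logical, whether each prediction matched a ground truth.
#' @param nGt number of ground-truth boxes of the class (> 0).
#' @param interpolation `"101point"` or `"allpoint"`.
#' @return AP as a unit fraction.
#' @export
averagePrecision <- function(conf, isTp, nGt,
                             interpolation = c("101point", "allpoint")) {
  interpolation <- match.arg(interpolation)
  if (nGt <= 0) stop("AP undefined: no ground truths for this class")
  if (!length(conf)) return(0)
  ord <- order(conf, decreasing = TRUE)
  tp <- cumsum(isTp[ord])
  fp <- cumsum(!isTp[ord])
  rec <- tp / nGt
  prec <- tp / (tp + fp)
  # monotone (non-increasing) precision envelope from the right
  env <- rev(cummax(rev(prec)))
  if (interpolation == "101point") {
    rgrid <- seq(0, 1, length.out = 101)
    # precision at recall >= r: first curve point with rec >= r
    idx <- findInterval(rgrid, rec, left.open = TRUE) + 1L
    pr <- ifelse(idx > length(env), 0, env[pmin(idx, length(env))])
    mean(pr)
  } else {
    r0 <- c(0, rec)
    sum((r0[-1] - r0[-length(r0)]) * env)
  }
}

#' Mean average precision (percent)
#'
#' Arithmetic mean of the per-class APs times 100; with the two pod classes
#' this is `(AP_G + AP_R) / 2 * 100`.
#'
#' @param apPerClass numeric vector of per-class APs (unit fractions).
#' @export
meanAveragePrecision <- function(apPerClass) {
  if (!length(apPerClass)) stop("empty AP list")
  100 * mean(apPerClass)
}

#' Is an image identified fully correctly?
#'
#' TRUE iff matching yields zero false positives and zero false negatives
#' for both classes — every pod of either class is found exactly once with
#' no spurious boxes. This is the per-image criterion behind the
#' image-level comparison precision.
#'
#' @inheritParams matchDetections
#' @export
imageLevelCorrect <- function(preds, gts, iouThresh = 0.5) {
  m <- matchDetections(preds, gts, iouThresh)
  sum(m$fp) == 0L && sum(m$fn) == 0L
}

#' Comparison precision (percent)
#'
#' Image-level accuracy `100 * AS / RS`, where AS counts images on which
#' the detector identified every pod of both classes correctly and RS the
#' images evaluated. Reported rounded half-up to 2 decimals.
#'
#' @param as_count images judged fully correct (AS).
#' @param rs_count images evaluated (RS).
#' @export
comparisonPrecision <- function(as_count, rs_count) {
  if (any(rs_count <= 0)) stop("RS must be positive")
  if (any(as_count < 0 | as_count > rs_count))
    stop("AS must lie in [0, RS]")
  floor(100 * as_count / rs_count * 100 + 0.5) / 100
}

#' k-fold cross-validation index partitions
#'
#' Seeded shuffle, then folds as equal as possible; each item appears in
#' exactly one validation fold.
#'
#' @param nItems number of items (>= k).
#' @param k number of folds (>= 2); 5 for the five-fold harness.
#' @param seed shuffle seed.
#' @return list of `k` lists with `train` and `validation` index vectors.
#' @export
kfoldSplits <- function(nItems, k = 5L, seed = 0L) {
  if (k < 2L) stop("k must be >= 2")
  if (nItems < k) stop("need at least k items")
  withSeed(seed, {
    ord <- sample(nItems)
    sizes <- diff(floor(seq(0, nItems, length.out = k + 1)))
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1) + 1L)
    lapply(seq_len(k), function(f) {
      val <- sort(ord[starts[f]:ends[f]])
      list(train = setdiff(seq_len(nItems), val), validation = val)
    })
  })
}

#' Evaluate detections over a dataset
#'
#' Pools predictions over images per class for AP (each prediction matched
#' greedily within its image at `iouThresh`), accumulates TP/FP/FN for
#' precision and recall, and counts fully correct images for the comparison
#' precision.
#'
#' @param predsList list of per-image detection tables.
#' @param gtsList list of per-image ground-truth tables (same order).
#' @param iouThresh matching IoU threshold.
#' @param interpolation AP interpolation mode, see [averagePrecision()].
#' @return list: per-class `ap`, `mAP` (%), `precision` (%), `recall` (%),
#'   `cp` (%), counts `tp/fp/fn`, and `tally` (AS, RS).
#' @export
evaluateDetections <- function(predsList, gtsList, iouThresh = 0.5,
                               interpolation = "101point") {
  stopifnot(length(predsList) == length(gtsList))
  classes <- POD_CLASSES
  pool <- list()
  tp <- fp <- fn <- setNames(integer(length(classes)), classes)
  as_count <- 0L
  for (i in seq_along(predsList)) {
    m <- matchDetections(predsList[[i]], gtsList[[i]], iouThresh)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (sum(m$fp) == 0L && sum(m$fn) == 0L) as_count <- as_count + 1L
    p <- predsList[[i]]
    if (nrow(p)) {
      p <- p[order(p$conf, decreasing = TRUE), , drop = FALSE]
      for (cl in classes) {
        pc <- p[p$cls == cl, , drop = FALSE]
        if (!nrow(pc)) next
        istp <- logical(nrow(pc))
        mm <- m$matches[m$matches$cls == cl, , drop = FALSE]
        istp[mm$pred] <- TRUE
        pool[[length(pool) + 1L]] <-
          data.frame(cls = cl, conf = pc$conf, tp = istp)
      }
    }
  }
  pool <- if (length(pool)) do.call(rbind, pool) else
    data.frame(cls = character(), conf = numeric(), tp = logical())
  ngt <- vapply(classes, function(cl)
    sum(vapply(gtsList, function(g) sum(g$cls == cl), 0L)), 0L)
  ap <- vapply(classes, function(cl) {
    if (ngt[cl] == 0) return(NA_real_)
    sub <- pool[pool$cls == cl, , drop = FALSE]
    averagePrecision(sub$conf, sub$tp, ngt[cl], interpolation)
  }, 0)
  list(ap = ap, mAP = meanAveragePrecision(ap[!is.na(ap)]),
       precision = if (sum(tp + fp) > 0) precisionPct(sum(tp), sum(fp)) else NA_real_,
       recall = if (sum(tp + fn) > 0) recallPct(sum(tp), sum(fn)) else NA_real_,
       cp = comparisonPrecision(as_count, length(predsList)),
       tp = tp, fp = fp, fn = fn,
       tally = c(AS = as_count, RS = length(predsList)))
}
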