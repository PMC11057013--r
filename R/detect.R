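# Decode raw head outputs to image-space detections and run per-class NMS.

decodeScale <- function(raw, anchors, stride, nc) {
  d <- dim(raw)                 # (Ho, Wo, na*(5+nc), 1)
  na <- nrow(anchors); per <- 5L + nc
  out <- vector("list", na)
  gy <- matrix(seq_len(d[1]) - 1L, d[1], d[2])        # row = y
  gx <- matrix(seq_len(d[2]) - 1L, d[1], d[2], byrow = TRUE)
  for (a in seq_len(na)) {
    off <- (a - 1L) * per
    tx <- sigmoid(raw[, , off + 1L, 1]); ty <- sigmoid(raw[, , off + 2L, 1])
    tw <- sigmoid(raw[, , off + 3L, 1]); th <- sigmoid(raw[, , off + 4L, 1])
    obj <- sigmoid(raw[, , off + 5L, 1])
    cls <- array(sigmoid(raw[, , off + 5L + seq_len(nc), 1]), c(d[1], d[2], nc))
    bx <- (2 * tx - 0.5 + gx) * stride
    by <- (2 * ty - 0.5 + gy) * stride
    bw <- (2 * tw)^2 * anchors[a, 1]
    bh <- (2 * th)^2 * anchors[a, 2]
    bestc <- apply(cls, c(1, 2), which.max)
    bestp <- apply(cls, c(1, 2), max)
    out[[a]] <- data.frame(cx = as.vector(bx), cy = as.vector(by),
                           w = as.vector(bw), h = as.vector(bh),
                           cls = POD_CLASSES[as.vector(bestc)],
                           conf = as.vector(obj * bestp),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Decode raw detector outputs and apply non-maximum suppression
#'
#' Anchor-relative offsets of the three head scales are decoded to
#' image-space center-format boxes; detections below the confidence
#' threshold are dropped and a greedy per-class NMS removes boxes whose IoU
#' with a higher-scoring surviving box of the same class exceeds
#' `iouThresh`.
#'
#' @param raws list of three raw head arrays (one image, batch axis 1).
#' @param detector the `podrotDetector` the outputs came from.
#' @param confThresh confidence threshold in `[0, 1]` (default 0.25).
#' @param iouThresh NMS IoU threshold in `[0, 1]` (default 0.45).
#' @return box table with columns `cx, cy, w, h, cls, conf`.
#' @export
decodeAndNms <- function(raws, detector, confThresh = 0.25, iouThresh = 0.45) {
  stopifnot(confThresh >= 0, confThresh <= 1, iouThresh >= 0, iouThresh <= 1)
  dets <- do.call(rbind, lapply(seq_along(raws), function(s)
    decodeScale(raws[[s]], detector$anchors[[s]], detector$strides[s],
                detector$numClasses)))
  dets <- dets[dets$conf >= confThresh & dets$w > 0 & dets$h > 0, , drop = FALSE]
  if (!nrow(dets)) return(makeBoxes())
  keep <- logical(nrow(dets))
  for (cl in unique(dets$cls)) {
    idx <- which(dets$cls == cl)
    idx <- idx[order(dets$conf[idx], decreasing = TRUE)]
    while (length(idx)) {
      i <- idx[1]; keep[i] <- TRUE; idx <- idx[-1]
      if (length(idx)) {
        ious <- iouMatrix(dets[i, , drop = FALSE], dets[idx, , drop = FALSE])
        idx <- idx[ious[1, ] <= iouThresh]
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the detector on one image
#'
#' Resizes the image to the detector input resolution if needed, runs the
#' forward pass in evaluation mode, decodes and suppresses, and maps boxes
#' back to the original pixel coordinates.
#'
#' @param detector a `podrotDetector`.
#' @param image `H x W x 3` array in `[0, 1]`, or an
#'   [AnnotatedImage][AnnotatedImage-class].
#' @inheritParams decodeAndNms
#' @return detection box table in original-image pixels.
#' @export
predictDetections <- function(detector, image, confThresh = 0.25,
                              iouThresh = 0.45) {
  if (is(image, "AnnotatedImage")) image <- imageData(image)
  d <- dim(image)
  sz <- detector$inputSize
  sx <- d[2] / sz; sy <- d[1] / sz
  if (d[1] != sz || d[2] != sz) image <- resizeImage(image, sz, sz)
  x <- array(image, c(sz, sz, 3, 1))
  fw <- netForward(detector, x, train = FALSE, keep = FALSE)
  dets <- decodeAndNms(fw$heads, detector, confThresh, iouThresh)
  if (nrow(dets)) {
    dets$cx <- dets$cx * sx; dets$w <- dets$w * sx
    dets$cy <- dets$cy * sy; dets$h <- dets$h * sy
  }
  dets
}
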