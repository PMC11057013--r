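#' Build a box table in center format
#'
#' Boxes follow the YOLO convention: center coordinates plus width and height
#' in continuous (pixel or normalized) units.
#'
#' @param cx,cy box center coordinates.
#' @param w,h box width and height (must be positive).
#' @param cls class labels, `"G"` (non-rotted) or `"R"` (rotten).
#' @param conf optional confidence scores in `[0, 1]`; `NA` for ground truth.
#' @return data.frame with columns `cx, cy, w, h, cls, conf`.
#' @examples
#' makeBoxes(c(10, 20), c(10, 20), 4, 4, cls = c("G", "R"))
#' @export
makeBoxes <- function(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), cls = character(), conf = NA_real_) {
  n <- length(cx)
  if (n > 0 && (any(w <= 0) || any(h <= 0)))
    stop("invalid box: width and height must be positive")
  if (n > 0 && length(cls) == 0) cls <- rep("G", n)
  data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
             w = rep_len(as.numeric(w), n), h = rep_len(as.numeric(h), n),
             cls = rep_len(as.character(cls), n),
             conf = rep_len(as.numeric(conf), n),
             stringsAsFactors = FALSE)
}

checkBox <- function(b) {
  if (any(b$w <= 0) || any(b$h <= 0))
    stop("invalid box: width and height must be positive")
  invisible(b)
}

#' Convert between center and corner box formats
#'
#' `centerToCorners()` maps `(cx, cy, w, h)` to `(xmin, ymin, xmax, ymax)`;
#' `cornersToCenter()` is its inverse.
#'
#' @param b data.frame of boxes in the respective source format.
#' @return data.frame in the other format, extra columns carried through.
#' @export
centerToCorners <- function(b) {
  out <- b
  out$xmin <- b$cx - b$w / 2; out$xmax <- b$cx + b$w / 2
  out$ymin <- b$cy - b$h / 2; out$ymax <- b$cy + b$h / 2
  out[c("xmin", "ymin", "xmax", "ymax",
        setdiff(names(b), c("cx", "cy", "w", "h")))]
}

#' @rdname centerToCorners
#' @export
cornersToCenter <- function(b) {
  out <- b
  out$cx <- (b$xmin + b$xmax) / 2; out$cy <- (b$ymin + b$ymax) / 2
  out$w <- b$xmax - b$xmin; out$h <- b$ymax - b$ymin
  out[c("cx", "cy", "w", "h",
        setdiff(names(b), c("xmin", "ymin", "xmax", "ymax")))]
}

# vectorized corner extents for single-row or matched-length box tables
.ext <- function(b) {
  list(x1 = b$cx - b$w / 2, x2 = b$cx + b$w / 2,
       y1 = b$cy - b$h / 2, y2 = b$cy + b$h / 2)
}

#' Intersection over union of two boxes
#'
#' @param a,b single-row box tables (or equal-length vectorized tables) in
#'   center format.
#' @return IoU value(s) in `[0, 1]`. Symmetric in its arguments.
#' @examples
#' boxIoU(makeBoxes(1, 1, 2, 2, "G"), makeBoxes(2, 2, 2, 2, "G"))  # 1/7
#' @export
boxIoU <- function(a, b) {
  checkBox(a); checkBox(b)
  ea <- .ext(a); eb <- .ext(b)
  iw <- pmax(0, pmin(ea$x2, eb$x2) - pmax(ea$x1, eb$x1))
  ih <- pmax(0, pmin(ea$y2, eb$y2) - pmax(ea$y1, eb$y1))
  inter <- iw * ih
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

# IoU matrix between two box tables (rows of a x rows of b)
iouMatrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ea <- .ext(a); eb <- .ext(b)
  iw <- pmax(0, outer(ea$x2, eb$x2, pmin) - outer(ea$x1, eb$x1, pmax))
  ih <- pmax(0, outer(ea$y2, eb$y2, pmin) - outer(ea$y1, eb$y1, pmax))
  inter <- iw * ih
  inter / (outer(a$w * a$h, b$w * b$h, `+`) - inter)
}
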