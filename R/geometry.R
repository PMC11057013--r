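#' Intermediate quantities of the CIoU/EIoU box-regression losses
#'
#' For a predicted box and a ground-truth box, computes the terms the two
#' localization losses are assembled from: the IoU, the squared distance
#' between box centers (rho^2), the width `c_w`, height `c_h` and squared
#' diagonal `c^2` of the smallest axis-aligned rectangle enclosing both
#' boxes, the aspect-ratio mismatch term
#' `v = 4/pi^2 (atan(w_gt/h_gt) - atan(w/h))^2`, and its piecewise weight
#' `alpha` (0 when IoU < 0.5, else `v / (1 - IoU + v)`).
#'
#' @param pred,gt single-row box tables in center format (see [makeBoxes()]).
#' @return list with elements `iou`, `center_dist_sq`, `enclosure_w`,
#'   `enclosure_h`, `enclosure_diag_sq`, `v`, `alpha`.
#' @seealso [ciouLoss()], [eiouLoss()]
#' @export
boxRegressionTerms <- function(pred, gt) {
  checkBox(pred); checkBox(gt)
  identical_box <- pred$cx == gt$cx & pred$cy == gt$cy &
    pred$w == gt$w & pred$h == gt$h
  iou <- boxIoU(pred, gt)
  ep <- .ext(pred); eg <- .ext(gt)
  cw <- pmax(ep$x2, eg$x2) - pmin(ep$x1, eg$x1)
  ch <- pmax(ep$y2, eg$y2) - pmin(ep$y1, eg$y1)
  rho2 <- (pred$cx - gt$cx)^2 + (pred$cy - gt$cy)^2
  v <- 4 / pi^2 * (atan(gt$w / gt$h) - atan(pred$w / pred$h))^2
  alpha <- ifelse(iou < 0.5, 0, v / (1 - iou + v))
  list(iou = iou,
       center_dist_sq = ifelse(identical_box, 0, rho2),
       enclosure_w = cw, enclosure_h = ch,
       enclosure_diag_sq = ifelse(identical_box, 0, cw^2 + ch^2),
       v = v, alpha = alpha)
}

.EPS_DENOM <- 1e-9

#' CIoU localization loss
#'
#' `1 - IoU + rho^2/c^2 + alpha * v`: the IoU complement plus a normalized
#' center-distance penalty and an aspect-ratio penalty weighted by the
#' piecewise `alpha` (zero when IoU < 0.5). Zero exactly when the two boxes
#' coincide.
#'
#' @inheritParams boxRegressionTerms
#' @return nonnegative scalar (vectorized over matched rows).
#' @examples
#' ciouLoss(makeBoxes(0, 0, 2, 2, "G"), makeBoxes(10, 0, 2, 2, "G"))  # 1 + 100/148
#' @export
ciouLoss <- function(pred, gt) {
  t <- boxRegressionTerms(pred, gt)
  ident <- t$iou == 1 & t$center_dist_sq == 0 & t$v == 0
  ifelse(ident, 0,
         1 - t$iou + t$center_dist_sq / (t$enclosure_diag_sq + .EPS_DENOM) +
           t$alpha * t$v)
}

#' EIoU localization loss
#'
#' Replaces CIoU's aspect-ratio term with the true width and height
#' differences: `1 - IoU + rho^2(b, b_gt)/c^2 + (w - w_gt)^2 / c_w^2 +
#' (h - h_gt)^2 / c_h^2`. The direct width/height penalties regress box size
#' without the aspect-ratio ambiguity of CIoU and are the localization loss
#' this package trains with by default.
#'
#' @inheritParams boxRegressionTerms
#' @return nonnegative scalar (vectorized over matched rows).
#' @examples
#' eiouLoss(makeBoxes(0, 0, 2, 2, "G"), makeBoxes(0, 0, 4, 4, "G"))  # 1.25
#' @export
eiouLoss <- function(pred, gt) {
  t <- boxRegressionTerms(pred, gt)
  ident <- t$iou == 1 & t$center_dist_sq == 0 &
    pred$w == gt$w & pred$h == gt$h
  ifelse(ident, 0,
         1 - t$iou +
           t$center_dist_sq / (t$enclosure_diag_sq + .EPS_DENOM) +
           (pred$w - gt$w)^2 / (t$enclosure_w^2 + .EPS_DENOM) +
           (pred$h - gt$h)^2 / (t$enclosure_h^2 + .EPS_DENOM))
}

#' Focal-weighted EIoU loss
#'
#' `IoU^gamma * EIoU(pred, gt)`: down-weights the regression loss of poorly
#' overlapping (mostly easy-negative) pairs so that well-overlapping hard
#' examples dominate. `gamma = 0` recovers the plain EIoU loss. Off by
#' default in training.
#'
#' @inheritParams boxRegressionTerms
#' @param gamma nonnegative focusing exponent.
#' @export
focalEiouLoss <- function(pred, gt, gamma = 0.5) {
  if (any(gamma < 0)) stop("gamma must be nonnegative")
  boxIoU(pred, gt)^gamma * eiouLoss(pred, gt)
}

#' Total detector loss composition
#'
#' The training loss is the weighted sum of the classification, localization
#' and confidence (objectness) components; all weights default to 1 so the
#' total is the plain sum of the three.
#'
#' @param parts list or numeric with elements/names `l_cla`, `l_loc`, `l_conf`.
#' @param weights length-3 numeric, per-component weights.
#' @return nonnegative scalar.
#' @export
totalLoss <- function(parts, weights = c(1, 1, 1)) {
  p <- unlist(parts[c("l_cla", "l_loc", "l_conf")])
  if (length(p) != 3 || anyNA(p)) stop("parts must contain l_cla, l_loc, l_conf")
  if (any(p < 0)) stop("invalid loss: components must be nonnegative")
  sum(weights * p)
}
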