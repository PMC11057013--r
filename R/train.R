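# Training: anchor/cell target assignment, loss with hand-assembled
# gradients for the head outputs, Adam updates.

# Assign ground-truth boxes (pixel units) to (scale, anchor, cell) slots.
# An anchor is responsible for a box when max(w/aw, aw/w, h/ah, ah/h) < ratio.
assignTargets <- function(gt, detector, ratio = 4) {
  res <- list()
  for (s in seq_along(detector$strides)) {
    st <- detector$strides[s]; A <- detector$anchors[[s]]
    grid <- detector$inputSize %/% st
    rows <- list()
    if (nrow(gt)) for (j in seq_len(nrow(gt))) {
      for (a in seq_len(nrow(A))) {
        r <- max(gt$w[j] / A[a, 1], A[a, 1] / gt$w[j],
                 gt$h[j] / A[a, 2], A[a, 2] / gt$h[j])
        if (r < ratio) {
          gx <- min(max(floor(gt$cx[j] / st), 0), grid - 1)
          gy <- min(max(floor(gt$cy[j] / st), 0), grid - 1)
          rows[[length(rows) + 1L]] <-
            data.frame(a = a, gx = gx, gy = gy, j = j)
        }
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(a = integer(), gx = integer(), gy = integer(), j = integer())
    # one target per (anchor, cell): keep the first claimant
    tab <- tab[!duplicated(tab[c("a", "gx", "gy")]), , drop = FALSE]
    res[[s]] <- tab
  }
  res
}

# central finite difference of the localization loss wrt the decoded box
boxLossGrad <- function(lossFn, pred, gt) {
  g <- numeric(4)
  for (k in 1:4) {
    v <- pred[[k]]
    hstep <- 1e-3 * max(1, abs(v))
    up <- pred; up[[k]] <- v + hstep
    dn <- pred; dn[[k]] <- max(v - hstep, if (k > 2) hstep else -Inf)
    g[k] <- (lossFn(up, gt) - lossFn(dn, gt)) / (up[[k]] - dn[[k]])
  }
  g
}

# loss + gradient seeds for the three raw head arrays of a batch.
detectionLoss <- function(heads, targets, detector,
                          lossType = c("eiou", "ciou"),
                          gains = c(box = 0.05, obj = 1, cls = 0.5)) {
  lossType <- match.arg(lossType)
  lf <- function(p, g) {
    pb <- list(cx = p[1], cy = p[2], w = p[3], h = p[4])
    gb <- list(cx = g[1], cy = g[2], w = g[3], h = g[4])
    if (lossType == "eiou") eiouLoss(pb, gb) else ciouLoss(pb, gb)
  }
  nc <- detector$numClasses; per <- 5L + nc
  balance <- c(4, 1, 0.4)
  N <- dim(heads[[1]])[4]
  grads <- lapply(heads, function(h) array(0, dim(h)))
  l_obj <- 0; l_cls <- 0; l_box <- 0
  npos_tot <- 0
  for (s in seq_along(heads)) {
    raw <- heads[[s]]
    d <- dim(raw); na <- nrow(detector$anchors[[s]])
    objch <- as.vector(outer(5L, (seq_len(na) - 1L) * per, `+`))
    to <- raw[, , objch, , drop = FALSE]
    po <- sigmoid(to)
    tgt <- array(0, dim(to))
    # positives: fill targets per image
    for (n in seq_len(N)) {
      tb <- targets[[n]]$scales[[s]]
      if (!nrow(tb)) next
      gt <- targets[[n]]$gt
      for (rr in seq_len(nrow(tb))) {
        a <- tb$a[rr]; gx <- tb$gx[rr]; gy <- tb$gy[rr]; j <- tb$j[rr]
        off <- (a - 1L) * per
        tgt[gy + 1L, gx + 1L, a, n] <- 1
        # ---- classification (BCE on the nc class logits)
        cls_idx <- off + 5L + seq_len(nc)
        z <- raw[gy + 1L, gx + 1L, cls_idx, n]
        pz <- sigmoid(z)
        y1 <- as.numeric(POD_CLASSES == gt$cls[j])
        l_cls <- l_cls - sum(y1 * log(pmax(pz, 1e-12)) +
                               (1 - y1) * log(pmax(1 - pz, 1e-12)))
        grads[[s]][gy + 1L, gx + 1L, cls_idx, n] <-
          grads[[s]][gy + 1L, gx + 1L, cls_idx, n] + (pz - y1)
        # ---- localization through the box decode
        st <- detector$strides[s]; A <- detector$anchors[[s]]
        t4 <- raw[gy + 1L, gx + 1L, off + 1:4, n]
        s4 <- sigmoid(t4)
        pred <- c((2 * s4[1] - 0.5 + gx) * st, (2 * s4[2] - 0.5 + gy) * st,
                  (2 * s4[3])^2 * A[a, 1], (2 * s4[4])^2 * A[a, 2])
        gvec <- c(gt$cx[j], gt$cy[j], gt$w[j], gt$h[j])
        l_box <- l_box + lf(pred, gvec)
        gb <- boxLossGrad(lf, pred, gvec)
        dpred_dt <- c(2 * s4[1] * (1 - s4[1]) * st,
                      2 * s4[2] * (1 - s4[2]) * st,
                      8 * s4[3]^2 * (1 - s4[3]) * A[a, 1],
                      8 * s4[4]^2 * (1 - s4[4]) * A[a, 2])
        grads[[s]][gy + 1L, gx + 1L, off + 1:4, n] <-
          grads[[s]][gy + 1L, gx + 1L, off + 1:4, n] + gb * dpred_dt
        npos_tot <- npos_tot + 1
      }
    }
    nobj <- length(to)
    l_obj <- l_obj + balance[s] *
      mean(-(tgt * log(pmax(po, 1e-12)) + (1 - tgt) * log(pmax(1 - po, 1e-12))))
    dobj <- balance[s] * (po - tgt) / nobj * gains["obj"]
    grads[[s]][, , objch, ] <- grads[[s]][, , objch, , drop = FALSE] + dobj
  }
  npos <- max(1, npos_tot)
  l_cla <- gains["cls"] * l_cls / (npos * nc)
  l_loc <- gains["box"] * l_box / npos
  l_conf <- gains["obj"] * l_obj
  # scale the positive-site gradients by the same normalizers
  for (s in seq_along(grads)) {
    d <- dim(grads[[s]]); na <- nrow(detector$anchors[[s]])
    objch <- as.vector(outer(5L, (seq_len(na) - 1L) * per, `+`))
    other <- setdiff(seq_len(d[3]), objch)
    cls_rel <- as.vector(outer(5L + seq_len(nc), (seq_len(na) - 1L) * per, `+`))
    box_rel <- as.vector(outer(1:4, (seq_len(na) - 1L) * per, `+`))
    grads[[s]][, , cls_rel, ] <- grads[[s]][, , cls_rel, ] *
      (gains["cls"] / (npos * nc))
    grads[[s]][, , box_rel, ] <- grads[[s]][, , box_rel, ] *
      (gains["box"] / npos)
  }
  list(parts = list(l_cla = unname(l_cla), l_loc = unname(l_loc),
                    l_conf = unname(l_conf)),
       total = unname(l_cla + l_loc + l_conf),
       grads = grads)
}

adamInit <- function(detector) {
  list(t = 0L, m = lapply(detector$nodes, function(nd)
    if (is.null(nd$params)) NULL else lapply(nd$params, function(p) p * 0)),
    v = lapply(detector$nodes, function(nd)
      if (is.null(nd$params)) NULL else lapply(nd$params, function(p) p * 0)))
}

adamStep <- function(detector, pgrads, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, clip = 10) {
  if (is.null(detector$opt)) detector$opt <- adamInit(detector)
  opt <- detector$opt
  gn2 <- 0
  for (i in seq_along(pgrads)) if (!is.null(pgrads[[i]]))
    for (g in pgrads[[i]]) if (!is.null(g)) gn2 <- gn2 + sum(g^2)
  sc <- if (sqrt(gn2) > clip) clip / sqrt(gn2) else 1
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (i in seq_along(detector$nodes)) {
    gi <- pgrads[[i]]
    if (is.null(gi)) next
    for (nm in names(gi)) {
      g <- gi[[nm]] * sc
      if (is.null(g)) next
      opt$m[[i]][[nm]] <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * g
      opt$v[[i]][[nm]] <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * g^2
      detector$nodes[[i]]$params[[nm]] <- detector$nodes[[i]]$params[[nm]] -
        lr * (opt$m[[i]][[nm]] / bc1) / (sqrt(opt$v[[i]][[nm]] / bc2) + eps)
    }
  }
  detector$opt <- opt
  detector
}

prepBatch <- function(anns, size) {
  N <- length(anns)
  x <- array(0, c(size, size, 3, N))
  targets <- vector("list", N)
  for (n in seq_len(N)) {
    ann <- anns[[n]]
    d <- dim(imageData(ann))
    a2 <- if (d[1] != size || d[2] != size)
      resizeWithBoxes(ann, size, size) else ann
    x[, , , n] <- imageData(a2)
    targets[[n]] <- list(gt = boxes(a2))
  }
  list(x = x, targets = targets)
}

#' One optimizer step on a batch of annotated images
#'
#' Runs the forward pass in training mode, computes the three-part detector
#' loss (BCE objectness on every cell, BCE classification and the selected
#' localization loss on assigned anchor/cell sites), backpropagates and
#' applies one Adam update.
#'
#' @param detector a `podrotDetector`.
#' @param batch list of [AnnotatedImage][AnnotatedImage-class]s.
#' @param lr learning rate.
#' @param lossType `"eiou"` (default) or `"ciou"`.
#' @param gains named loss-component weights (box/obj/cls).
#' @return list with the updated `detector`, the loss `parts`
#'   (`l_cla`, `l_loc`, `l_conf`) and their `total`.
#' @export
trainStep <- function(detector, batch, lr = 0.01, lossType = "eiou",
                      gains = c(box = 0.05, obj = 1, cls = 0.5)) {
  if (!length(batch)) stop("empty batch")
  pb <- prepBatch(batch, detector$inputSize)
  for (n in seq_along(pb$targets))
    pb$targets[[n]]$scales <- assignTargets(pb$targets[[n]]$gt, detector)
  fw <- netForward(detector, pb$x, train = TRUE)
  detector$nodes <- fw$nodes          # persist BN running stats
  dl <- detectionLoss(fw$heads, pb$targets, detector, lossType)
  pgrads <- netBackward(detector, fw, dl$grads)
  detector <- adamStep(detector, pgrads, lr)
  list(detector = detector, parts = dl$parts, total = dl$total)
}

#' Train a detector on a set of annotated images
#'
#' Mini-batch Adam training; images are shuffled each epoch with the given
#' seed. Defaults mirror the full-scale configuration (200 epochs, batch 32,
#' initial learning rate 0.01); smoke-scale runs override them.
#'
#' @inheritParams trainStep
#' @param anns list of `AnnotatedImage`s (ground-truth boxes attached).
#' @param epochs,batchSize,lr training schedule.
#' @param seed shuffle seed.
#' @param verbose print per-epoch mean loss.
#' @return list with the trained `detector` and a data.frame `history`
#'   (epoch, step, l_cla, l_loc, l_conf, total).
#' @export
fitDetector <- function(detector, anns, epochs = 200L, batchSize = 32L,
                        lr = 0.01, lossType = "eiou", seed = 0L,
                        verbose = FALSE) {
  if (!length(anns)) stop("empty training set")
  hist <- list()
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(anns))
      bs <- split(ord, ceiling(seq_along(ord) / batchSize))
      for (k in seq_along(bs)) {
        st <- trainStep(detector, anns[bs[[k]]], lr = lr, lossType = lossType)
        detector <- st$detector
        hist[[length(hist) + 1L]] <-
          data.frame(epoch = ep, step = k, l_cla = st$parts$l_cla,
                     l_loc = st$parts$l_loc, l_conf = st$parts$l_conf,
                     total = st$total)
      }
      if (verbose) {
        h <- do.call(rbind, hist)
        message(sprintf("epoch %d: mean total loss %.4f", ep,
                        mean(h$total[h$epoch == ep])))
      }
    }
  })
  list(detector = detector, history = do.call(rbind, hist))
}
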