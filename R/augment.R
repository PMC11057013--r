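# The seven augmentation primitives of the dataset pipeline. Each primitive
# transforms pixels and boxes consistently; boxes whose remaining visible
# area falls below `minVisible` (default 25%) after crop/cutout/geometric
# clipping are dropped.

AUG_OPS <- c("noise", "cutout", "rotation", "cropping", "translation",
             "hflip", "vflip")

defaultAugConfig <- function() {
  list(noise_sd = c(5, 15) / 255,    # Gaussian, 8-bit scale 5..15
       cutout_n = 3L, cutout_frac = 0.10,
       rotation_deg = 15,
       crop_min = 0.7,
       translate_frac = 0.2,
       minVisible = 0.25,
       bg = 0.5)
}

clipBoxes <- function(b, W, H, areaBefore, minVisible) {
  if (!nrow(b)) return(b)
  cc <- centerToCorners(b)
  cc$xmin <- pmax(cc$xmin, 0); cc$ymin <- pmax(cc$ymin, 0)
  cc$xmax <- pmin(cc$xmax, W); cc$ymax <- pmin(cc$ymax, H)
  vis <- pmax(0, cc$xmax - cc$xmin) * pmax(0, cc$ymax - cc$ymin)
  keep <- vis >= minVisible * areaBefore & vis > 0
  cornersToCenter(cc[keep, , drop = FALSE])
}

augRotate <- function(img, b, angle, bg) {
  d <- dim(img); H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  ctr <- c((W + 1) / 2, (H + 1) / 2)
  # inverse mapping with nearest neighbor; feature at q maps to R(th) q
  co <- cos(th); si <- sin(th)
  xy <- expand.grid(r = seq_len(H), c = seq_len(W))
  dx <- xy$c - ctr[1]; dy <- xy$r - ctr[2]
  sx <- round(co * dx + si * dy + ctr[1])
  sy <- round(-si * dx + co * dy + ctr[2])
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  out <- array(bg, d)
  for (ch in 1:3) {
    plane <- img[, , ch]
    o <- rep(bg, H * W)
    o[ok] <- plane[cbind(sy[ok], sx[ok])]
    out[, , ch] <- matrix(o, H, W)
  }
  if (nrow(b)) {
    cc <- centerToCorners(b)
    nb <- b
    for (i in seq_len(nrow(b))) {
      px <- c(cc$xmin[i], cc$xmax[i], cc$xmin[i], cc$xmax[i]) - ctr[1]
      py <- c(cc$ymin[i], cc$ymin[i], cc$ymax[i], cc$ymax[i]) - ctr[2]
      rx <- co * px - si * py + ctr[1]
      ry <- si * px + co * py + ctr[2]
      nb$cx[i] <- mean(range(rx)); nb$cy[i] <- mean(range(ry))
      nb$w[i] <- diff(range(rx)); nb$h[i] <- diff(range(ry))
    }
    b <- nb
  }
  list(img = out, b = b)
}

augTranslate <- function(img, b, dx, dy, bg) {
  d <- dim(img); H <- d[1]; W <- d[2]
  out <- array(bg, d)
  sr <- seq_len(H) - dy; sc <- seq_len(W) - dx
  okr <- sr >= 1 & sr <= H; okc <- sc >= 1 & sc <= W
  out[which(okr), which(okc), ] <- img[sr[okr], sc[okc], , drop = FALSE]
  b$cx <- b$cx + dx; b$cy <- b$cy + dy
  list(img = out, b = b)
}

augCutout <- function(img, b, n, frac, bg, minVisible) {
  d <- dim(img); H <- d[1]; W <- d[2]
  covered <- rep(0, nrow(b))
  areas <- b$w * b$h
  for (k in seq_len(n)) {
    s <- max(2L, round(runif(1, 0.3, 1) * frac * W))
    x0 <- sample.int(W - s + 1L, 1L); y0 <- sample.int(H - s + 1L, 1L)
    img[y0:(y0 + s - 1L), x0:(x0 + s - 1L), ] <- bg
    if (nrow(b)) {
      cc <- centerToCorners(b)
      iw <- pmax(0, pmin(cc$xmax, x0 + s - 1) - pmax(cc$xmin, x0 - 1))
      ih <- pmax(0, pmin(cc$ymax, y0 + s - 1) - pmax(cc$ymin, y0 - 1))
      covered <- covered + iw * ih       # upper bound when squares overlap
    }
  }
  if (nrow(b)) {
    keep <- (areas - covered) >= minVisible * areas
    b <- b[keep, , drop = FALSE]
  }
  list(img = img, b = b)
}

augCrop <- function(img, b, cropMin, minVisible) {
  d <- dim(img); H <- d[1]; W <- d[2]
  fw <- runif(1, cropMin, 1); fh <- runif(1, cropMin, 1)
  cw <- max(8L, round(W * fw)); ch <- max(8L, round(H * fh))
  x0 <- sample.int(W - cw + 1L, 1L); y0 <- sample.int(H - ch + 1L, 1L)
  sub <- img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
  areas <- b$w * b$h
  b$cx <- b$cx - (x0 - 1L); b$cy <- b$cy - (y0 - 1L)
  b <- clipBoxes(b, cw, ch, areas, minVisible)
  # scale back to the original canvas so all outputs share one size
  sx <- W / cw; sy <- H / ch
  img2 <- resizeImage(sub, H, W)
  b$cx <- b$cx * sx; b$w <- b$w * sx
  b$cy <- b$cy * sy; b$h <- b$h * sy
  list(img = img2, b = b)
}

#' Apply augmentation primitives to an annotated image
#'
#' Applies the requested subset of the seven primitives (`noise`, `cutout`,
#' `rotation`, `cropping`, `translation`, `hflip`, `vflip`) in that fixed
#' canonical order, deterministically for a given seed. Boxes are
#' transformed together with the pixels; boxes retaining less than
#' `config$minVisible` (default 25%) of their area after cropping or cutout
#' are dropped. Magnitudes (noise sigma 5-15 on the 8-bit scale, rotation
#' within +-15 degrees, up to 3 cutout squares of at most 10% image width,
#' crop scale at least 0.7, translation up to 20%) are configurable.
#'
#' @param ann an [AnnotatedImage][AnnotatedImage-class].
#' @param ops character vector, subset of the seven primitive names.
#' @param seed RNG seed making the result reproducible.
#' @param config magnitude configuration, see `defaultAugConfig()`.
#' @return augmented `AnnotatedImage`.
#' @export
augmentImage <- function(ann, ops, seed = 0L, config = defaultAugConfig()) {
  ops <- match.arg(ops, AUG_OPS, several.ok = TRUE)
  if (!length(ops)) stop("ops must be non-empty")
  img <- imageData(ann); b <- boxes(ann)
  d <- dim(img); H <- d[1]; W <- d[2]
  withSeed(seed, {
    for (op in AUG_OPS[AUG_OPS %in% ops]) {
      if (op == "noise") {
        sd <- runif(1, config$noise_sd[1], config$noise_sd[2])
        img <- pmin(pmax(img + array(rnorm(length(img), sd = sd), dim(img)), 0), 1)
      } else if (op == "cutout") {
        r <- augCutout(img, b, config$cutout_n, config$cutout_frac,
                       config$bg, config$minVisible)
        img <- r$img; b <- r$b
      } else if (op == "rotation") {
        ang <- runif(1, -config$rotation_deg, config$rotation_deg)
        r <- augRotate(img, b, ang, config$bg)
        img <- r$img
        b <- clipBoxes(r$b, W, H, r$b$w * r$b$h, config$minVisible)
      } else if (op == "cropping") {
        r <- augCrop(img, b, config$crop_min, config$minVisible)
        img <- r$img; b <- r$b
      } else if (op == "translation") {
        dx <- sample(seq(-round(W * config$translate_frac),
                         round(W * config$translate_frac)), 1)
        dy <- sample(seq(-round(H * config$translate_frac),
                         round(H * config$translate_frac)), 1)
        areas <- b$w * b$h
        r <- augTranslate(img, b, dx, dy, config$bg)
        img <- r$img
        b <- clipBoxes(r$b, W, H, areas, config$minVisible)
      } else if (op == "hflip") {
        img <- img[, rev(seq_len(W)), , drop = FALSE]
        b$cx <- W - b$cx
      } else if (op == "vflip") {
        img <- img[rev(seq_len(H)), , , drop = FALSE]
        b$cy <- H - b$cy
      }
    }
  })
  AnnotatedImage(img, b, sourceId(ann))
}

#' Random combination of augmentation primitives
#'
#' Samples `nOps` distinct primitives uniformly from the seven available
#' (seeded) and applies them in the fixed canonical order via
#' [augmentImage()]. `nOps = 0` returns the input unchanged.
#'
#' @inheritParams augmentImage
#' @param nOps number of primitives to combine (0..7); the dataset pipeline
#'   uses 5.
#' @export
randomAugment <- function(ann, nOps = 5L, seed = 0L,
                          config = defaultAugConfig()) {
  stopifnot(nOps >= 0, nOps <= 7)
  if (nOps == 0L) return(ann)
  withSeed(seed, {
    ops <- sample(AUG_OPS, nOps)
    augmentImage(ann, ops, seed = sample.int(.Machine$integer.max, 1L),
                 config = config)
  })
}
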