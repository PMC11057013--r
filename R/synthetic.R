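# Synthetic pod-rot scenes: tan (non-rotted) and dark mottled (rotten)
# elliptical pods on a soil-toned background with curvilinear root/stem
# distractor strokes that deliberately share the rotten palette. Three
# adhesion strata control pairwise box overlap: none (all IoU 0), slight
# (at least one pair in (0, 0.3], none above), severe (at least one pair
# above 0.3).

POD_COL <- list(G = c(0.82, 0.70, 0.45), R = c(0.33, 0.21, 0.12))
SOIL_COL <- c(0.52, 0.42, 0.33)
ADHESION_SLIGHT_MAX <- 0.3

podBox <- function(cx, cy, a, b, th) {
  hw <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hh <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  c(cx = cx, cy = cy, w = 2 * hw, h = 2 * hh)
}

drawEllipse <- function(img, cx, cy, a, b, th, col, mottle) {
  d <- dim(img); H <- d[1]; W <- d[2]
  x0 <- max(1L, floor(cx - a - b)); x1 <- min(W, ceiling(cx + a + b))
  y0 <- max(1L, floor(cy - a - b)); y1 <- min(H, ceiling(cy + a + b))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  gy <- matrix(ys, length(ys), length(xs)) - cy
  u <- cos(th) * gx + sin(th) * gy
  v <- -sin(th) * gx + cos(th) * gy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  n_in <- sum(inside)
  if (!n_in) return(img)
  shade <- 1 - 0.35 * ((u / a)^2 + (v / b)^2)[inside]   # simple lambertian dome
  spots <- if (mottle)
    0.55 * (runif(n_in) < 0.25) else 0.12 * (runif(n_in) < 0.15)
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    val <- col[ch] * shade * (1 - spots) +
      rnorm(n_in, sd = 0.02)
    plane[inside] <- pmin(pmax(val, 0), 1)
    img[ys, xs, ch] <- plane
  }
  img
}

drawStroke <- function(img, col) {
  d <- dim(img); H <- d[1]; W <- d[2]
  n <- 80L
  t <- seq(0, 1, length.out = n)
  x0 <- runif(1, 1, W); y0 <- runif(1, 1, H)
  ang <- runif(1, 0, 2 * pi)
  len <- runif(1, 0.3, 0.8) * min(W, H)
  amp <- runif(1, 2, 12)
  px <- x0 + cos(ang) * t * len + amp * sin(t * runif(1, 2, 6) * pi) * cos(ang + pi / 2)
  py <- y0 + sin(ang) * t * len + amp * sin(t * runif(1, 2, 6) * pi) * sin(ang + pi / 2)
  wdt <- runif(1, 1, 2.5)
  for (k in seq_len(n)) {
    xs <- round(px[k] + seq(-wdt, wdt)); ys <- round(py[k] + seq(-wdt, wdt))
    xs <- xs[xs >= 1 & xs <= W]; ys <- ys[ys >= 1 & ys <= H]
    if (length(xs) && length(ys))
      for (ch in 1:3)
        img[ys, xs, ch] <- col[ch] * runif(1, 0.8, 1.1)
  }
  img
}

#' Generate one synthetic pod-rot scene
#'
#' Draws `nPods` elliptical pods (exactly `round(nPods * rottenFraction)` of
#' them rotten) over a noisy soil background with root/stem distractor
#' strokes, placing pods so the pairwise ground-truth box IoUs satisfy the
#' requested adhesion stratum. Deterministic for a given seed; the returned
#' annotation holds the exact tight boxes of the drawn ellipses.
#'
#' @param spec a [SceneSpec][SceneSpec-class].
#' @param maxTries placement retries per pod before a placement error.
#' @return an [AnnotatedImage][AnnotatedImage-class].
#' @export
generateScene <- function(spec, maxTries = 300L) {
  stopifnot(is(spec, "SceneSpec"))
  withSeed(spec@seed, {
    H <- spec@height; W <- spec@width
    img <- array(rep(SOIL_COL, each = H * W), c(H, W, 3)) +
      array(rnorm(H * W * 3, sd = 0.04), c(H, W, 3))
    img <- pmin(pmax(img, 0), 1)
    nStrokes <- round(spec@distractorDensity * 6)
    for (k in seq_len(nStrokes))
      img <- drawStroke(img, POD_COL$R * runif(1, 0.8, 1.2))
    nR <- round(spec@nPods * spec@rottenFraction)
    cls <- c(rep("R", nR), rep("G", spec@nPods - nR))
    cls <- sample(cls)
    placed <- NULL
    geom <- list()
    base_r <- min(W, H) / 16
    for (i in seq_len(spec@nPods)) {
      ok <- FALSE
      for (tr in seq_len(maxTries)) {
        a <- runif(1, 1.2, 1.9) * base_r
        b <- runif(1, 0.7, 1.0) * base_r
        th <- runif(1, 0, pi)
        # the first pod of a slight/severe scene pair is forced adjacent
        forcePair <- i == 2L && spec@adhesion != "none"
        if (forcePair) {
          ref <- geom[[1]]
          off <- if (spec@adhesion == "slight") runif(1, 1.6, 2.1) else runif(1, 0.5, 0.9)
          ang <- runif(1, 0, 2 * pi)
          cx <- ref$cx + cos(ang) * off * base_r
          cy <- ref$cy + sin(ang) * off * base_r
        } else {
          cx <- runif(1, a + 2, W - a - 2)
          cy <- runif(1, a + 2, H - a - 2)
        }
        if (cx < a + 1 || cx > W - a - 1 || cy < a + 1 || cy > H - a - 1) next
        bx <- podBox(cx, cy, a, b, th)
        cand <- as.data.frame(as.list(bx))
        if (!is.null(placed)) {
          ious <- iouMatrix(cand, placed)[1, ]
          mx <- max(ious)
          bad <- switch(spec@adhesion,
            none = mx > 0,
            slight = mx > ADHESION_SLIGHT_MAX ||
              (forcePair && (mx <= 0 || mx > ADHESION_SLIGHT_MAX)),
            severe = (forcePair && mx <= ADHESION_SLIGHT_MAX) ||
              (!forcePair && mx > 0.65))
          if (bad) next
        }
        placed <- rbind(placed, cand)
        geom[[i]] <- list(cx = cx, cy = cy, a = a, b = b, th = th)
        ok <- TRUE
        break
      }
      if (!ok) stop(sprintf(
        "placement error: could not place pod %d/%d (adhesion '%s') after %d tries",
        i, spec@nPods, spec@adhesion, maxTries))
    }
    for (i in seq_along(geom)) {
      g <- geom[[i]]
      img <- drawEllipse(img, g$cx, g$cy, g$a, g$b, g$th,
                         POD_COL[[cls[i]]], mottle = cls[i] == "R")
    }
    b <- makeBoxes(placed$cx, placed$cy, placed$w, placed$h, cls = cls)
    AnnotatedImage(img, b, sprintf("scene_%s_seed%d", spec@adhesion, spec@seed))
  })
}

#' Generate a stratified synthetic validation set
#'
#' `nPerStratum` scenes for each adhesion stratum (none, slight, severe)
#' with per-scene seeds derived from `seed`; the layout mirrors the
#' image-level validation design (50 per stratum, 150 images, at full
#' scale).
#'
#' @param nPerStratum scenes per stratum.
#' @param baseSpec template [SceneSpec][SceneSpec-class]; its seed is
#'   replaced per scene.
#' @param seed master seed.
#' @return list of [AnnotatedImage][AnnotatedImage-class]s with a
#'   `stratum` attribute.
#' @export
generateValidationSet <- function(nPerStratum = 50L, baseSpec = sceneSpec(),
                                  seed = 0L) {
  stopifnot(nPerStratum >= 1)
  strata <- c("none", "slight", "severe")
  out <- list(); labels <- character()
  k <- 0L
  for (s in strata) {
    for (i in seq_len(nPerStratum)) {
      k <- k + 1L
      sp <- new("SceneSpec", nPods = baseSpec@nPods,
                rottenFraction = baseSpec@rottenFraction, adhesion = s,
                width = baseSpec@width, height = baseSpec@height,
                seed = as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647),
                distractorDensity = baseSpec@distractorDensity)
      out[[k]] <- generateScene(sp)
      labels[k] <- s
    }
  }
  attr(out, "stratum") <- labels
  out
}

#' Grade scenes from their ground-truth labels
#'
#' The perfect-detector oracle: grading computed directly from the
#' ground-truth boxes of each scene, closing the loop between the scene
#' generator and the grading module.
#'
#' @param scenes list of [AnnotatedImage][AnnotatedImage-class]s.
#' @return data.frame of grade records.
#' @export
groundTruthGrading <- function(scenes) {
  do.call(rbind, lapply(scenes, function(s)
    recordFromDetections(sourceId(s), boxes(s))))
}

#' Write a scene set to disk
#'
#' PNG image, VOC XML and YOLO txt per scene plus a manifest CSV listing
#' stratum, counts, rate and grade.
#'
#' @param scenes list of scenes from [generateValidationSet()].
#' @param dir output directory.
#' @export
writeSceneSet <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strata <- attr(scenes, "stratum") %||% rep(NA_character_, length(scenes))
  rows <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    id <- sprintf("img%04d", i)
    sc@sourceId <- id
    writeImagePNG(imageData(sc), file.path(dir, paste0(id, ".png")))
    writeVocXml(sc, file.path(dir, paste0(id, ".xml")))
    writeYoloTxt(sc, file.path(dir, paste0(id, ".txt")))
    r <- recordFromDetections(id, boxes(sc))
    r$stratum <- strata[i]
    rows[[i]] <- r
  }
  man <- do.call(rbind, rows)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
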