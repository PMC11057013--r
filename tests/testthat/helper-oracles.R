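# Independent oracles used across the suite.

# IoU by rasterization: overlay both boxes on a fine grid spanning their
# union and count covered cells.
rasterIoU <- function(a, b, n = 2000L) {
  xr <- range(a$cx - a$w / 2, a$cx + a$w / 2, b$cx - b$w / 2, b$cx + b$w / 2)
  yr <- range(a$cy - a$h / 2, a$cy + a$h / 2, b$cy - b$h / 2, b$cy + b$h / 2)
  # cell midpoints of an n x n grid over the joint extent
  hx <- diff(xr) / n; hy <- diff(yr) / n
  xs <- seq(xr[1] + hx / 2, xr[2] - hx / 2, length.out = n)
  ys <- seq(yr[1] + hy / 2, yr[2] - hy / 2, length.out = n)
  inA_x <- xs >= a$cx - a$w / 2 & xs <= a$cx + a$w / 2
  inA_y <- ys >= a$cy - a$h / 2 & ys <= a$cy + a$h / 2
  inB_x <- xs >= b$cx - b$w / 2 & xs <= b$cx + b$w / 2
  inB_y <- ys >= b$cy - b$h / 2 & ys <= b$cy + b$h / 2
  nA <- sum(inA_x) * as.numeric(sum(inA_y))
  nB <- sum(inB_x) * as.numeric(sum(inB_y))
  nI <- sum(inA_x & inB_x) * as.numeric(sum(inA_y & inB_y))
  nI / (nA + nB - nI)
}

randomBox <- function(lim = 50) {
  makeBoxes(runif(1, -lim, lim), runif(1, -lim, lim),
            runif(1, 0.5, lim / 2), runif(1, 0.5, lim / 2), "G")
}

# Brute-force 101-point AP: for each recall level take the maximum precision
# over every curve point whose recall reaches it, by direct double loop over
# all prediction prefixes.
bruteForceAP <- function(conf, isTp, nGt) {
  ord <- order(conf, decreasing = TRUE)
  isTp <- isTp[ord]
  n <- length(isTp)
  recs <- precs <- numeric(n)
  for (i in seq_len(n)) {
    tp <- sum(isTp[seq_len(i)])
    recs[i] <- tp / nGt
    precs[i] <- tp / i
  }
  rgrid <- seq(0, 1, length.out = 101)
  vals <- vapply(rgrid, function(r) {
    sel <- recs >= r
    if (!any(sel)) 0 else max(precs[sel])
  }, 0)
  mean(vals)
}

# extract one stored (uncompressed) entry from a PKZIP container by name;
# independent reader used to validate the spreadsheet the package writes
readStoredZipEntry <- function(path, name) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2)
  pos <- 1L
  repeat {
    if (pos + 30 > length(raw)) stop("entry not found: ", name)
    sig <- u32(pos)
    if (sig != 0x04034b50) stop("not a local file header at offset ", pos)
    csize <- u32(pos + 18)
    nlen <- u16(pos + 26); xlen <- u16(pos + 28)
    nm <- rawToChar(raw[pos + 30 + seq_len(nlen) - 1])
    dstart <- pos + 30 + nlen + xlen
    if (nm == name) return(raw[dstart + seq_len(csize) - 1])
    pos <- dstart + csize
  }
}

# tiny annotated image fixture: gray canvas with given boxes
tinyAnn <- function(boxes, H = 64L, W = 64L, id = "fix") {
  AnnotatedImage(array(0.5, c(H, W, 3)), boxes, id)
}

# small scene list shared by metric/pipeline tests
smallSceneSet <- function(nPerStratum = 2L, nPods = 6L, size = 160L, seed = 11L) {
  generateValidationSet(nPerStratum,
                        sceneSpec(nPods = nPods, rottenFraction = 0.3,
                                  width = size, height = size),
                        seed = seed)
}
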