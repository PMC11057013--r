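# Annotation and image I/O. VOC XML corner coordinates are treated as
# 1-based inclusive pixel corners; the continuous center format used
# internally is cx = (xmin - 1 + xmax)/2, w = xmax - xmin + 1 ... simplified
# to the conventional half-open reading: w = xmax - xmin, cx = (xmin+xmax)/2.

#' Read a Pascal VOC XML annotation
#'
#' Parses object names (must be `"G"` or `"R"`), converts corner boxes to
#' center format and returns the annotation metadata; the image itself is
#' read separately (see [readImagePNG()]).
#'
#' @param path path to the XML file.
#' @return list with `sourceId`, `width`, `height`, and a `boxes` table.
#' @export
readVocXml <- function(path) {
  doc <- xml2::read_xml(path)
  fn <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs)) {
    nm <- xml2::xml_text(xml2::xml_find_first(objs, "./name"))
    bad <- setdiff(unique(nm), POD_CLASSES)
    if (length(bad))
      stop(sprintf("unknown class name(s) in %s: %s", basename(path),
                   paste(bad, collapse = ", ")))
    num <- function(tag) as.numeric(xml2::xml_text(
      xml2::xml_find_first(objs, paste0("./bndbox/", tag))))
    corners <- data.frame(xmin = num("xmin"), ymin = num("ymin"),
                          xmax = num("xmax"), ymax = num("ymax"),
                          cls = nm, conf = NA_real_)
    b <- cornersToCenter(corners)
  } else b <- makeBoxes()
  list(sourceId = if (is.na(fn)) basename(path) else fn,
       width = w, height = h, boxes = b)
}

#' Write a Pascal VOC XML annotation
#'
#' @param ann an [AnnotatedImage][AnnotatedImage-class].
#' @param path output path.
#' @export
writeVocXml <- function(ann, path) {
  d <- dim(imageData(ann))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(sourceId(ann), ".png"))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(d[2]))
  xml2::xml_add_child(sz, "height", as.character(d[1]))
  xml2::xml_add_child(sz, "depth", "3")
  b <- centerToCorners(boxes(ann))
  for (i in seq_len(nrow(b))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", b$cls[i])
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(b$xmin[i], digits = 10))
    xml2::xml_add_child(bb, "ymin", format(b$ymin[i], digits = 10))
    xml2::xml_add_child(bb, "xmax", format(b$xmax[i], digits = 10))
    xml2::xml_add_child(bb, "ymax", format(b$ymax[i], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write YOLO-format label lines
#'
#' One line per box: `class cx cy w h`, all coordinates normalized to
#' `[0, 1]` by the image dimensions; class index 0 is G (non-rotted),
#' 1 is R (rotten). Boxes extending past the image are clipped with a
#' warning.
#'
#' @param ann an [AnnotatedImage][AnnotatedImage-class].
#' @param path output path.
#' @export
writeYoloTxt <- function(ann, path) {
  d <- dim(imageData(ann)); W <- d[2]; H <- d[1]
  b <- boxes(ann)
  if (nrow(b)) {
    cc <- centerToCorners(b)
    if (any(cc$xmin < 0 | cc$ymin < 0 | cc$xmax > W | cc$ymax > H)) {
      warning("boxes outside image bounds clipped during YOLO export")
      cc$xmin <- pmax(cc$xmin, 0); cc$ymin <- pmax(cc$ymin, 0)
      cc$xmax <- pmin(cc$xmax, W); cc$ymax <- pmin(cc$ymax, H)
      b <- cornersToCenter(cc)
    }
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     match(b$cls, POD_CLASSES) - 1L,
                     b$cx / W, b$cy / H, b$w / W, b$h / H)
  } else lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format label lines
#'
#' @param path label file path.
#' @param width,height image dimensions used to denormalize; leave `NULL`
#'   to keep normalized coordinates.
#' @return box table in center format.
#' @export
readYoloTxt <- function(path, width = NULL, height = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(makeBoxes())
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  W <- width %||% 1; H <- height %||% 1
  makeBoxes(m[, 2] * W, m[, 3] * H, m[, 4] * W, m[, 5] * H,
            cls = POD_CLASSES[m[, 1] + 1L],
            conf = if (ncol(m) >= 6) m[, 6] else NA_real_)
}

#' Read / write an image as PNG
#' @param path file path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] |> array(c(dim(img)[1:2], 3))
}

#' @rdname readImagePNG
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Resize an annotated image, scaling boxes accordingly
#'
#' @param ann an [AnnotatedImage][AnnotatedImage-class].
#' @param targetW,targetH target size in pixels.
#' @export
resizeWithBoxes <- function(ann, targetW, targetH) {
  stopifnot(targetW > 0, targetH > 0)
  d <- dim(imageData(ann))
  sx <- targetW / d[2]; sy <- targetH / d[1]
  img <- resizeImage(imageData(ann), targetH, targetW)
  b <- boxes(ann)
  b$cx <- b$cx * sx; b$w <- b$w * sx
  b$cy <- b$cy * sy; b$h <- b$h * sy
  AnnotatedImage(img, b, sourceId(ann))
}

resizeImage <- function(img, H, W) {
  eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = W, h = H)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Seeded train/test split
#'
#' Shuffles item indices with the given seed and partitions them so that
#' `round(n * ratio)` items land in the training set (the 9:1 default of the
#' dataset pipeline) and the remainder in the test set.
#'
#' @param items vector or list of items.
#' @param ratio training fraction in (0, 1); default 0.9.
#' @param seed shuffle seed.
#' @return list with `train` and `test` subsets (same type as `items`).
#' @export
splitDataset <- function(items, ratio = 0.9, seed = 0L) {
  n <- length(items)
  if (!n) stop("empty input: nothing to split")
  stopifnot(ratio > 0, ratio < 1)
  withSeed(seed, {
    ord <- sample(n)
    ntr <- round(n * ratio)
    list(train = items[ord[seq_len(ntr)]],
         test = items[ord[setdiff(seq_len(n), seq_len(ntr))]])
  })
}

#' Label census over annotations
#'
#' Counts G and R labels. Accepts a character/factor vector of class
#' labels, a box table, an [AnnotatedImage][AnnotatedImage-class], or a
#' list of any of these; counts are additive over shards.
#'
#' @param x annotations in any of the accepted forms.
#' @return named list with `n_G`, `n_R`, `total`.
#' @export
labelCensus <- function(x) {
  collect <- function(e) {
    if (is(e, "AnnotatedImage")) return(boxes(e)$cls)
    if (is.data.frame(e)) return(e$cls)
    if (is.list(e)) return(unlist(lapply(e, collect)))
    as.character(e)
  }
  cls <- collect(x)
  n_G <- sum(cls == "G"); n_R <- sum(cls == "R")
  list(n_G = n_G, n_R = n_R, total = n_G + n_R)
}
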