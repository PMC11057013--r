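#' @import methods
#' @importFrom stats rnorm runif setNames quantile
#' @importFrom utils write.csv read.csv head tail
#' @useDynLib podrot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

POD_CLASSES <- c("G", "R")

#' Annotated image: RGB raster plus pod bounding boxes
#'
#' The central data container: an RGB image (numeric array `height x width x 3`
#' with values in `[0, 1]`) together with a box table in continuous center
#' format. One row of `boxes` holds `cx, cy, w, h` in pixel units, the pod
#' class (`"G"` non-rotted, `"R"` rotten) and an optional detection
#' confidence in `[0, 1]` (`NA` for ground-truth boxes).
#'
#' @slot image numeric array, `H x W x 3`, values in `[0, 1]`.
#' @slot boxes data.frame with columns `cx, cy, w, h, cls, conf`.
#' @slot sourceId character scalar identifying the image.
#'
#' @examples
#' ann <- AnnotatedImage(array(0.5, c(32, 32, 3)),
#'                       makeBoxes(16, 16, 10, 8, cls = "G"), "demo")
#' nBoxes(ann)
#' @export
setClass("AnnotatedImage",
  representation(image = "array", boxes = "data.frame", sourceId = "character"))

setValidity("AnnotatedImage", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  b <- object@boxes
  need <- c("cx", "cy", "w", "h", "cls", "conf")
  if (!all(need %in% names(b)))
    msg <- c(msg, sprintf("boxes must have columns %s", paste(need, collapse = ", ")))
  else {
    if (nrow(b) && any(b$w <= 0 | b$h <= 0))
      msg <- c(msg, "box widths and heights must be positive")
    if (nrow(b) && !all(b$cls %in% POD_CLASSES))
      msg <- c(msg, sprintf("unknown class label(s): %s",
                            paste(unique(setdiff(b$cls, POD_CLASSES)), collapse = ", ")))
    cf <- b$conf[!is.na(b$conf)]
    if (length(cf) && any(cf < 0 | cf > 1))
      msg <- c(msg, "confidences must lie in [0, 1]")
  }
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "sourceId must be a single string")
  if (length(msg)) msg else TRUE
})

#' @rdname AnnotatedImage-class
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param boxes box table as built by [makeBoxes()].
#' @param sourceId image identifier.
#' @export
AnnotatedImage <- function(image, boxes = makeBoxes(), sourceId = "image") {
  new("AnnotatedImage", image = image, boxes = boxes, sourceId = sourceId)
}

#' Parameters of one synthetic pod-rot scene
#'
#' Describes a synthetic image of a pod cluster: how many pods, the fraction
#' that are rotten, the adhesion stratum (how strongly pod bounding boxes are
#' allowed/required to overlap), canvas size, distractor stroke density and
#' the RNG seed making the scene reproducible.
#'
#' @slot nPods integer, number of pods drawn (>= 1).
#' @slot rottenFraction numeric in `[0, 1]`; `round(nPods * rottenFraction)`
#'   pods are drawn rotten.
#' @slot adhesion one of `"none"`, `"slight"`, `"severe"`.
#' @slot width,height canvas size in pixels.
#' @slot seed integer RNG seed.
#' @slot distractorDensity nonnegative scalar scaling the number of root/stem
#'   strokes drawn in the background.
#' @export
setClass("SceneSpec",
  representation(nPods = "integer", rottenFraction = "numeric",
                 adhesion = "character", width = "integer", height = "integer",
                 seed = "integer", distractorDensity = "numeric"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@nPods < 1L) msg <- c(msg, "nPods must be >= 1")
  if (object@rottenFraction < 0 || object@rottenFraction > 1)
    msg <- c(msg, "rottenFraction must lie in [0, 1]")
  if (!object@adhesion %in% c("none", "slight", "severe"))
    msg <- c(msg, "adhesion must be one of none/slight/severe")
  if (object@width < 32L || object@height < 32L)
    msg <- c(msg, "canvas must be at least 32 x 32")
  if (object@distractorDensity < 0) msg <- c(msg, "distractorDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SceneSpec-class
#' @param nPods number of pods.
#' @param rottenFraction fraction of pods drawn rotten.
#' @param adhesion adhesion stratum.
#' @param width,height canvas size in pixels.
#' @param seed RNG seed.
#' @param distractorDensity density of background strokes.
#' @export
sceneSpec <- function(nPods = 12L, rottenFraction = 0.3,
                      adhesion = c("none", "slight", "severe"),
                      width = 320L, height = 320L, seed = 1L,
                      distractorDensity = 1) {
  new("SceneSpec", nPods = as.integer(nPods), rottenFraction = rottenFraction,
      adhesion = match.arg(adhesion), width = as.integer(width),
      height = as.integer(height), seed = as.integer(seed),
      distractorDensity = distractorDensity)
}

#' Architecture specification of the detector
#'
#' An ordered stage list in the YOLO configuration dialect: each stage is a
#' list with `from` (input stage indices, `-1` = previous), `kind`
#' (`conv`, `C3`, `SPPF`, `SA`, `upsample`, `concat`, `detect`), output
#' channels and stage-specific settings, plus a `section` tag
#' (`backbone`/`head`). The class also carries input size, class count,
#' anchor boxes per output scale, and the three head strides.
#'
#' @slot stages list of stage descriptors.
#' @slot inputSize integer, square input resolution in pixels.
#' @slot numClasses integer class count (2: non-rotted / rotten).
#' @slot anchors list of three `n x 2` matrices of anchor `(w, h)` in pixels.
#' @slot strides integer vector, strides of the three detection scales.
#' @slot variant character tag (e.g. `"tiny"`, `"small"`).
#' @export
setClass("ArchSpec",
  representation(stages = "list", inputSize = "integer", numClasses = "integer",
                 anchors = "list", strides = "integer", variant = "character"))

setValidity("ArchSpec", function(object) {
  msg <- character()
  if (length(object@anchors) != length(object@strides))
    msg <- c(msg, "one anchor matrix per stride required")
  if (length(object@strides) != 3L || !all(object@strides == c(8L, 16L, 32L)))
    msg <- c(msg, "exactly three head scales with strides 8/16/32 expected")
  kinds <- vapply(object@stages, `[[`, "", "kind")
  if (!any(kinds == "detect")) msg <- c(msg, "spec must end in a detect stage")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@image)
  tab <- table(factor(object@boxes$cls, POD_CLASSES))
  cat(sprintf("AnnotatedImage '%s': %d x %d px, %d boxes (G: %d, R: %d)\n",
              object@sourceId, d[2], d[1], nrow(object@boxes), tab["G"], tab["R"]))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d pods (rotten fraction %.2f), adhesion '%s', %dx%d, seed %d\n",
              object@nPods, object@rottenFraction, object@adhesion,
              object@width, object@height, object@seed))
})

setMethod("show", "ArchSpec", function(object) {
  kinds <- vapply(object@stages, `[[`, "", "kind")
  cat(sprintf("ArchSpec '%s': %d stages (%s), input %d, %d classes\n",
              object@variant, length(object@stages),
              paste(sprintf("%s:%d", names(table(kinds)), table(kinds)), collapse = " "),
              object@inputSize, object@numClasses))
})

#' @rdname AnnotatedImage-class
#' @param object,x an `AnnotatedImage`.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("imageData", "AnnotatedImage", function(x) x@image)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("boxes", "AnnotatedImage", function(x) x@boxes)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("sourceId", "AnnotatedImage", function(x) x@sourceId)

#' @rdname AnnotatedImage-class
#' @export
nBoxes <- function(x) nrow(boxes(x))
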