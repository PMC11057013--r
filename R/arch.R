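STOCK_ANCHORS <- list(
  matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
  matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
  matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))

stg <- function(from, kind, section, channels = NA_integer_, k = 1L,
                stride = 1L, n = 1L, shortcut = TRUE, groups = NA_integer_) {
  list(from = as.integer(from), kind = kind, section = section,
       channels = as.integer(channels), k = as.integer(k),
       stride = as.integer(stride), n = as.integer(n),
       shortcut = shortcut, groups = as.integer(groups))
}

#' Architecture specification of the YOLOv5s-style detector
#'
#' Returns the stage list of the CSP backbone (stem conv, four
#' stride-halving conv stages each followed by a C3 block, SPPF), the
#' PAN-style feature-fusion neck and the three-scale coupled prediction head
#' (strides 8/16/32). Two widths are provided: `"small"` is the standard
#' small-model scaling (backbone C3 widths 64/128/256/512); `"tiny"` divides
#' all widths by 8 and uses single-bottleneck C3 stages so the network
#' trains in minutes on one CPU — the scale all smoke experiments use.
#'
#' Use [insertSAAfterC3()] to obtain the attention-augmented (ES) variant.
#'
#' @param variant `"tiny"` or `"small"`.
#' @param inputSize square input resolution (default 640 for small,
#'   320 for tiny).
#' @param numClasses class count (default 2: G / R).
#' @return an [ArchSpec][ArchSpec-class].
#' @export
yoloArchSpec <- function(variant = c("tiny", "small"), inputSize = NULL,
                         numClasses = 2L) {
  variant <- match.arg(variant)
  if (variant == "small") {
    w <- c(32L, 64L, 128L, 256L, 512L); d <- c(1L, 2L, 3L, 1L)
  } else {
    w <- c(8L, 16L, 32L, 64L, 128L); d <- c(1L, 1L, 1L, 1L)
  }
  if (is.null(inputSize)) inputSize <- if (variant == "small") 640L else 320L
  nk <- w[4]; nk2 <- w[3]                     # neck widths
  stages <- list(
    stg(-1, "conv", "backbone", w[1], k = 6L, stride = 2L),        # 0 P1
    stg(-1, "conv", "backbone", w[2], k = 3L, stride = 2L),        # 1 P2
    stg(-1, "C3", "backbone", w[2], n = d[1]),                     # 2
    stg(-1, "conv", "backbone", w[3], k = 3L, stride = 2L),        # 3 P3
    stg(-1, "C3", "backbone", w[3], n = d[2]),                     # 4
    stg(-1, "conv", "backbone", w[4], k = 3L, stride = 2L),        # 5 P4
    stg(-1, "C3", "backbone", w[4], n = d[3]),                     # 6
    stg(-1, "conv", "backbone", w[5], k = 3L, stride = 2L),        # 7 P5
    stg(-1, "C3", "backbone", w[5], n = d[4]),                     # 8
    stg(-1, "SPPF", "backbone", w[5], k = 5L),                     # 9
    stg(-1, "conv", "head", nk),                                   # 10
    stg(-1, "upsample", "head"),                                   # 11
    stg(c(-1L, 6L), "concat", "head"),                             # 12
    stg(-1, "C3", "head", nk, n = d[1], shortcut = FALSE),         # 13
    stg(-1, "conv", "head", nk2),                                  # 14
    stg(-1, "upsample", "head"),                                   # 15
    stg(c(-1L, 4L), "concat", "head"),                             # 16
    stg(-1, "C3", "head", nk2, n = d[1], shortcut = FALSE),        # 17 P3 out
    stg(-1, "conv", "head", nk2, k = 3L, stride = 2L),             # 18
    stg(c(-1L, 14L), "concat", "head"),                            # 19
    stg(-1, "C3", "head", nk, n = d[1], shortcut = FALSE),         # 20 P4 out
    stg(-1, "conv", "head", nk, k = 3L, stride = 2L),              # 21
    stg(c(-1L, 10L), "concat", "head"),                            # 22
    stg(-1, "C3", "head", w[5], n = d[1], shortcut = FALSE),       # 23 P5 out
    stg(c(17L, 20L, 23L), "detect", "head"))
  new("ArchSpec", stages = stages, inputSize = as.integer(inputSize),
      numClasses = as.integer(numClasses), anchors = STOCK_ANCHORS,
      strides = c(8L, 16L, 32L), variant = variant)
}

#' Insert a Shuffle Attention block after every backbone C3 stage
#'
#' Produces the attention-augmented (ES-style) architecture: each backbone
#' C3 stage is immediately followed by one SA block of matching width, so
#' local CSP features pass through grouped channel/spatial attention before
#' the neck consumes them. Neck C3 stages are untouched. Cross-stage
#' references in the neck are remapped to the SA outputs.
#'
#' @param base an [ArchSpec][ArchSpec-class] without SA blocks.
#' @param groups SA group count `G`; every backbone C3 width must be
#'   divisible by `2 * groups`.
#' @return a new `ArchSpec` tagged `<variant>-ES`.
#' @export
insertSAAfterC3 <- function(base, groups = 4L) {
  stages <- base@stages
  kinds <- vapply(stages, `[[`, "", "kind")
  secs <- vapply(stages, `[[`, "", "section")
  c3 <- which(kinds == "C3" & secs == "backbone")
  if (!length(c3)) stop("spec error: no backbone C3 stages to attach SA to")
  if (any(kinds == "SA"))
    stop("spec error: SA blocks already present; refusing a second insertion")
  # map old stage index (1-based) -> new index after insertions
  newmap <- seq_along(stages) + vapply(seq_along(stages),
                                       function(i) sum(c3 < i), 0L)
  out <- vector("list", length(stages) + length(c3))
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    st$from <- vapply(st$from, function(f) {
      if (f < 0) return(f)
      nf <- newmap[f + 1L] - 1L            # back to 0-based
      if ((f + 1L) %in% c3) nf <- nf + 1L  # redirect to the SA output
      as.integer(nf)
    }, 0L)
    out[[newmap[i]]] <- st
    if (i %in% c3)
      out[[newmap[i] + 1L]] <- stg(-1, "SA", "backbone", st$channels,
                                   groups = groups)
  }
  new("ArchSpec", stages = out, inputSize = base@inputSize,
      numClasses = base@numClasses, anchors = base@anchors,
      strides = base@strides, variant = paste0(base@variant, "-ES"))
}

#' Count backbone C3 stages / SA blocks of a spec
#' @param spec an `ArchSpec`.
#' @export
countStages <- function(spec) {
  kinds <- vapply(spec@stages, `[[`, "", "kind")
  secs <- vapply(spec@stages, `[[`, "", "section")
  c(backboneC3 = sum(kinds == "C3" & secs == "backbone"),
    SA = sum(kinds == "SA"))
}

#' Serialize an ArchSpec to YAML (and back)
#'
#' @param spec an `ArchSpec`.
#' @param path file path.
#' @export
archToYAML <- function(spec, path) {
  obj <- list(variant = spec@variant, input_size = spec@inputSize,
              num_classes = spec@numClasses,
              strides = as.integer(spec@strides),
              anchors = lapply(spec@anchors, function(m) as.vector(t(m))),
              stages = lapply(spec@stages, function(st) {
                st$from <- as.list(st$from); st
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname archToYAML
#' @export
archFromYAML <- function(path) {
  obj <- yaml::read_yaml(path)
  stages <- lapply(obj$stages, function(st) {
    st$from <- as.integer(unlist(st$from))
    st$channels <- as.integer(st$channels)
    st$k <- as.integer(st$k); st$stride <- as.integer(st$stride)
    st$n <- as.integer(st$n); st$groups <- as.integer(st$groups)
    st
  })
  new("ArchSpec", stages = stages, inputSize = as.integer(obj$input_size),
      numClasses = as.integer(obj$num_classes),
      anchors = lapply(obj$anchors, function(v) matrix(v, ncol = 2, byrow = TRUE)),
      strides = as.integer(obj$strides), variant = obj$variant)
}
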