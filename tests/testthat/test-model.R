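# helper: logits that decode to a chosen box size under a given anchor
invSizeLogit <- function(target, anchor) {
  s <- sqrt(target / (4 * anchor))
  stopifnot(s < 1)
  stats::qlogis(s)
}

test_that("SA insertion follows every backbone C3 stage exactly once", {
  for (v in c("tiny", "small")) {
    base <- yoloArchSpec(v)
    expect_equal(unname(countStages(base)["SA"]), 0)
    es <- insertSAAfterC3(base, groups = 4)
    cs <- countStages(es)
    expect_equal(unname(cs["backboneC3"]), 4)
    expect_equal(unname(cs["SA"]), 4)        # one SA per backbone C3
    kinds <- vapply(es@stages, `[[`, "", "kind")
    secs <- vapply(es@stages, `[[`, "", "section")
    after <- kinds[which(kinds == "C3" & secs == "backbone") + 1L]
    expect_true(all(after == "SA"))
    # neck C3 stages untouched
    expect_false(any(kinds[secs == "head"] == "SA"))
    # double insertion is refused
    expect_error(insertSAAfterC3(es, 4), "already present")
  }
  # a spec without backbone C3 stages is rejected
  noc3 <- yoloArchSpec("tiny")
  noc3@stages <- Filter(function(s) !(s$kind == "C3" && s$section == "backbone"),
                        noc3@stages)
  expect_error(insertSAAfterC3(noc3, 4), "no backbone C3")
})

test_that("detector outputs three scales at strides 8/16/32", {
  det <- buildDetector(yoloArchSpec("tiny", inputSize = 640L), seed = 1)
  ns <- asNamespace("podrot")
  x <- array(runif(640 * 640 * 3 * 2), c(640, 640, 3, 2))
  fw <- ns$netForward(det, x, train = FALSE, keep = FALSE)
  dims <- lapply(fw$heads, dim)
  expect_equal(vapply(dims, `[[`, 0L, 1), c(80L, 40L, 20L))   # 640 / (8,16,32)
  expect_equal(vapply(dims, `[[`, 0L, 2), c(80L, 40L, 20L))
  expect_true(all(vapply(dims, `[[`, 0L, 3) == 3 * (5 + 2)))
  expect_true(all(vapply(dims, `[[`, 0L, 4) == 2L))           # batch carried
  # evaluation-mode forward is deterministic
  fw2 <- ns$netForward(det, x, train = FALSE, keep = FALSE)
  expect_identical(fw$heads, fw2$heads)
})

test_that("ES parameter count exceeds baseline by the analytic SA delta", {
  base <- buildDetector(yoloArchSpec("tiny"), seed = 1)
  es <- buildDetector(insertSAAfterC3(yoloArchSpec("tiny"), groups = 4), seed = 1)
  widths <- c(16, 32, 64, 128)                 # tiny backbone C3 widths
  expect_equal(countParams(es) - countParams(base),
               sum(vapply(widths, saParamCount, 0, groups = 4)))
})

test_that("architecture specs round-trip through YAML", {
  es <- insertSAAfterC3(yoloArchSpec("tiny"), groups = 4)
  f <- withr::local_tempfile(fileext = ".yaml")
  archToYAML(es, f)
  back <- archFromYAML(f)
  expect_equal(back@strides, es@strides)
  expect_equal(back@anchors, es@anchors)
  expect_equal(length(back@stages), length(es@stages))
  expect_equal(vapply(back@stages, `[[`, "", "kind"),
               vapply(es@stages, `[[`, "", "kind"))
  d1 <- buildDetector(es, seed = 2); d2 <- buildDetector(back, seed = 2)
  expect_equal(countParams(d1), countParams(d2))
})

test_that("decode and NMS suppress duplicates but keep distinct classes", {
  det <- buildDetector(yoloArchSpec("tiny"), seed = 1)
  emptyRaws <- lapply(c(40, 20, 10), function(g) array(-20, c(g, g, 21, 1)))
  expect_equal(nrow(decodeAndNms(emptyRaws, det)), 0)

  # same cell, two anchors decoding to the identical box, same class
  raws <- lapply(c(40, 20, 10), function(g) array(-20, c(g, g, 21, 1)))
  A <- det$anchors[[1]]
  per <- 7
  mk <- function(anchor_i, obj, cls_logits) {
    off <- (anchor_i - 1) * per
    raws[[1]][6, 6, off + 1, 1] <<- 0                      # tx: center offset 0
    raws[[1]][6, 6, off + 2, 1] <<- 0
    raws[[1]][6, 6, off + 3, 1] <<- invSizeLogit(30, A[anchor_i, 1])
    raws[[1]][6, 6, off + 4, 1] <<- invSizeLogit(30, A[anchor_i, 2])
    raws[[1]][6, 6, off + 5, 1] <<- stats::qlogis(obj)
    raws[[1]][6, 6, off + 5 + 1:2, 1] <<- cls_logits
  }
  mk(1, 0.9, c(10, -10))      # class G, conf ~0.9
  mk(2, 0.8, c(10, -10))      # identical box, class G, conf ~0.8
  out <- decodeAndNms(raws, det, confThresh = 0.25, iouThresh = 0.45)
  expect_equal(nrow(out), 1)
  expect_equal(out$conf, 0.9, tolerance = 1e-3)
  expect_equal(out$cls, "G")
  expect_equal(out$cx, 5.5 * 8, tolerance = 1e-6)          # cell (6,6), stride 8
  expect_equal(out$w, 30, tolerance = 1e-6)

  # identical boxes of different classes both survive per-class NMS
  mk(2, 0.8, c(-10, 10))      # same box, class R
  out2 <- decodeAndNms(raws, det, confThresh = 0.25, iouThresh = 0.45)
  expect_equal(sort(out2$cls), c("G", "R"))
  # threshold drops the weaker one
  out3 <- decodeAndNms(raws, det, confThresh = 0.85, iouThresh = 0.45)
  expect_equal(out3$cls, "G")
})

test_that("a training step returns a consistent loss breakdown and updates", {
  scenes <- smallSceneSet(1)
  spec <- insertSAAfterC3(yoloArchSpec("tiny", inputSize = 160L), groups = 4)
  det <- buildDetector(spec, seed = 3)
  expect_error(trainStep(det, list()), "empty batch")
  st <- trainStep(det, scenes[1:2], lr = 0.003)
  expect_true(is.finite(st$total))
  expect_gte(st$total, 0)
  expect_equal(st$total,
               totalLoss(st$parts), tolerance = 1e-12)
  # parameters actually moved
  expect_false(identical(st$detector$nodes[[1]]$params$w, det$nodes[[1]]$params$w))
  # both loss dialects run
  st2 <- trainStep(det, scenes[1:2], lr = 0.003, lossType = "ciou")
  expect_true(is.finite(st2$total))
})

test_that("repeated steps on one small batch drive the loss down", {
  scenes <- smallSceneSet(1)[1:3]
  spec <- insertSAAfterC3(yoloArchSpec("tiny", inputSize = 160L), groups = 4)
  det <- buildDetector(spec, seed = 4)
  losses <- numeric(24)
  for (k in seq_along(losses)) {
    st <- trainStep(det, scenes, lr = 0.003)
    det <- st$detector
    losses[k] <- st$total
  }
  sm <- stats::filter(losses, rep(1 / 5, 5), sides = 1)
  expect_lt(sm[length(losses)], sm[5])        # smoothed decrease
  expect_lt(losses[24], losses[1])
})

test_that("localization loss vanishes when decoded predictions equal targets", {
  # hand-build one positive site whose logits decode exactly to the target box
  det <- buildDetector(yoloArchSpec("tiny", inputSize = 160L), seed = 5)
  ns <- asNamespace("podrot")
  gt <- makeBoxes(44, 44, 30, 30, "G")     # cell (5,5) at stride 8, offset 0.5
  targets <- list(list(gt = gt, scales = ns$assignTargets(gt, det)))
  raws <- lapply(c(20, 10, 5), function(g) array(-20, c(g, g, 21, 1)))
  for (s in 1:3) {
    tb <- targets[[1]]$scales[[s]]
    if (!nrow(tb)) next
    A <- det$anchors[[s]]; st <- det$strides[s]
    for (r in seq_len(nrow(tb))) {
      off <- (tb$a[r] - 1) * 7
      # (2*sig(t) - 0.5 + g) * stride = 44  =>  sig(t) = (44/st - g + 0.5)/2
      sx <- (44 / st - tb$gx[r] + 0.5) / 2
      raws[[s]][tb$gy[r] + 1, tb$gx[r] + 1, off + 1, 1] <- stats::qlogis(sx)
      raws[[s]][tb$gy[r] + 1, tb$gx[r] + 1, off + 2, 1] <- stats::qlogis(sx)
      raws[[s]][tb$gy[r] + 1, tb$gx[r] + 1, off + 3, 1] <- invSizeLogit(30, A[tb$a[r], 1])
      raws[[s]][tb$gy[r] + 1, tb$gx[r] + 1, off + 4, 1] <- invSizeLogit(30, A[tb$a[r], 2])
    }
  }
  dl <- ns$detectionLoss(raws, list(list(gt = gt,
                                         scales = targets[[1]]$scales)),
                         det, "eiou")
  expect_lt(dl$parts$l_loc, 1e-8)
})
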